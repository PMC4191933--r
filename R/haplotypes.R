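#' Construct a set of phased haplotypes aligned to a marker map
#'
#' Haplotypes are stored as a character matrix, one row per haplotype and
#' one column per marker in map order; `NA` encodes a missing (unsequenced)
#' call, which is always kept distinct from every allele token. SNP alleles
#' are single nucleotides; DIP (deletion/insertion polymorphism) alleles
#' are opaque tokens such as `"del"` or `"ins:TTC"`, compared only by exact
#' string equality.
#'
#' @param alleles Character matrix, rows = haplotypes, columns = markers in
#'   map order. `NA` = missing.
#' @param map A [marker_map()] the columns are aligned to.
#' @param haplotype_id Character vector of unique row identifiers.
#' @param source Provenance of each haplotype: one of `"pedigree_founder"`,
#'   `"homozygous_sample"`, `"reference"`, `"synthetic_truth"`. Recycled if
#'   length 1.
#' @param group_id CEH group label per haplotype, `NA` when unassigned.
#' @return A `haplotype_set`: a list with elements `alleles` (the matrix,
#'   rownames = `haplotype_id`) and `info` (data frame `haplotype_id`,
#'   `source`, `group_id`).
#' @export
haplotype_set <- function(alleles, map, haplotype_id = rownames(alleles),
                          source = "pedigree_founder", group_id = NA_character_) {
  stopifnot(inherits(map, "marker_map"))
  alleles <- as.matrix(alleles)
  mode(alleles) <- "character"
  if (ncol(alleles) != nrow(map)) {
    stop("haplotype matrix has ", ncol(alleles), " columns but map has ",
         nrow(map), " markers")
  }
  if (is.null(haplotype_id)) {
    haplotype_id <- paste0("H", seq_len(nrow(alleles)))
  }
  haplotype_id <- as.character(haplotype_id)
  if (anyDuplicated(haplotype_id)) stop("duplicate haplotype_id")
  if (length(haplotype_id) != nrow(alleles)) {
    stop("haplotype_id length does not match number of rows")
  }
  source <- rep_len(as.character(source), nrow(alleles))
  bad_src <- setdiff(unique(source),
                     c("pedigree_founder", "homozygous_sample", "reference",
                       "synthetic_truth"))
  if (length(bad_src) > 0L) {
    stop("unknown haplotype source: ", paste(bad_src, collapse = ", "))
  }
  group_id <- rep_len(as.character(group_id), nrow(alleles))
  validate_alleles(alleles, map)
  rownames(alleles) <- haplotype_id
  colnames(alleles) <- map$marker_id
  structure(
    list(alleles = alleles,
         info = data.frame(haplotype_id = haplotype_id, source = source,
                           group_id = group_id, stringsAsFactors = FALSE)),
    class = "haplotype_set"
  )
}

# SNP calls must be single nucleotides; DIP tokens any non-empty string.
validate_alleles <- function(alleles, map) {
  snp <- map$kind == "SNP"
  if (any(snp)) {
    v <- alleles[, snp, drop = FALSE]
    bad <- !is.na(v) & !(v %in% c("A", "C", "G", "T"))
    if (any(bad)) {
      j <- which(snp)[col(v)[bad][1L]]
      stop("invalid SNP allele token '", v[bad][1L], "' at marker ",
           map$marker_id[j])
    }
  }
  dip <- map$kind == "DIP"
  if (any(dip)) {
    v <- alleles[, dip, drop = FALSE]
    bad <- !is.na(v) & !nzchar(v)
    if (any(bad)) {
      j <- which(dip)[col(v)[bad][1L]]
      stop("empty DIP allele token at marker ", map$marker_id[j])
    }
  }
  invisible(TRUE)
}

#' Number of haplotypes in a set
#' @param haps A `haplotype_set`.
#' @return Integer count.
#' @export
n_haplotypes <- function(haps) nrow(haps$alleles)

#' Subset a haplotype set by row
#' @param haps A `haplotype_set`.
#' @param which Row indices, logical mask, or haplotype ids.
#' @return A `haplotype_set` with the selected haplotypes.
#' @export
subset_haplotypes <- function(haps, which) {
  if (is.character(which)) which <- match(which, haps$info$haplotype_id)
  structure(list(alleles = haps$alleles[which, , drop = FALSE],
                 info = haps$info[which, , drop = FALSE]),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d markers (%d group-assigned)\n",
              nrow(x$alleles), ncol(x$alleles), sum(!is.na(x$info$group_id))))
  invisible(x)
}

#' Read a phased haplotype matrix from a tab-separated file
#'
#' Rows are haplotypes; the first column is `haplotype_id`, optional
#' reserved columns `source` and `group_id` follow, and the remaining
#' columns are marker ids. Columns may appear in any order relative to the
#' map: alleles are realigned to map order on load. The file may carry a
#' comment directive `#default_row: <haplotype_id>` naming a row (typically
#' the human reference haplotype) whose allele fills any empty cell in the
#' same column — the convention used by haplotype tables that only print
#' deviations from the reference sequence.
#'
#' @param path Path to the TSV file.
#' @param map A [marker_map()] giving marker order and kinds.
#' @param missing_token Token encoding a missing call (default `"NA"`).
#' @return A [haplotype_set()] aligned to `map`.
#' @export
read_haplotype_matrix <- function(path, map, missing_token = "NA") {
  stopifnot(inherits(map, "marker_map"))
  lines <- readLines(path)
  default_row <- NA_character_
  hdr <- grep("^#default_row:", lines, value = TRUE)
  if (length(hdr) > 0L) {
    default_row <- trimws(sub("^#default_row:", "", hdr[1L]))
  }
  lines <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"haplotype_id" %in% names(tab)) {
    stop("haplotype matrix lacks a haplotype_id column")
  }
  reserved <- intersect(c("haplotype_id", "source", "group_id"), names(tab))
  marker_cols <- setdiff(names(tab), reserved)
  unknown <- setdiff(marker_cols, map$marker_id)
  if (length(unknown) > 0L) {
    stop("column(s) not in marker map: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(tab)
  alleles <- matrix(NA_character_, nrow = n, ncol = nrow(map),
                    dimnames = list(tab$haplotype_id, map$marker_id))
  for (mc in marker_cols) alleles[, mc] <- tab[[mc]]
  if (!is.na(default_row)) {
    ridx <- match(default_row, tab$haplotype_id)
    if (is.na(ridx)) stop("default_row '", default_row, "' not found in file")
    empty <- !is.na(alleles) & alleles == ""
    fill <- matrix(rep(alleles[ridx, ], each = n), nrow = n)
    alleles[empty] <- fill[empty]
  }
  if (any(alleles == "", na.rm = TRUE)) {
    stop("empty cells present but no #default_row directive declared")
  }
  alleles[alleles == missing_token] <- NA_character_
  src <- if ("source" %in% names(tab)) tab$source else "pedigree_founder"
  grp <- if ("group_id" %in% names(tab)) {
    ifelse(tab$group_id %in% c("", "."), NA_character_, tab$group_id)
  } else NA_character_
  haplotype_set(alleles, map, haplotype_id = tab$haplotype_id,
                source = src, group_id = grp)
}

#' Write a haplotype matrix to a tab-separated file
#'
#' Inverse of [read_haplotype_matrix()]: columns are written in map order
#' with the reserved columns `haplotype_id`, `source`, `group_id` first,
#' and every cell written explicitly so that a read of the output
#' reproduces the input exactly.
#'
#' @param haps A [haplotype_set()] aligned to `map`.
#' @param map The [marker_map()].
#' @param path Output file path.
#' @param missing_token Token to write for missing calls (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_haplotype_matrix <- function(haps, map, path, missing_token = "NA") {
  stopifnot(inherits(haps, "haplotype_set"), inherits(map, "marker_map"))
  if (ncol(haps$alleles) != nrow(map) ||
      !identical(colnames(haps$alleles), map$marker_id)) {
    stop("haplotype set is not aligned to the supplied marker map")
  }
  m <- haps$alleles
  m[is.na(m)] <- missing_token
  out <- data.frame(haplotype_id = haps$info$haplotype_id,
                    source = haps$info$source,
                    group_id = ifelse(is.na(haps$info$group_id), ".",
                                      haps$info$group_id),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(m, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
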