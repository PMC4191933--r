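#' Construct a marker map
#'
#' The marker map is the coordinate backbone of every analysis: an ordered
#' set of polymorphic sites (SNPs and deletion/insertion polymorphisms,
#' DIPs) with 1-based GRCh37 chromosome-6 positions, the amplicon each site
#' was resequenced in, and an optional sub-region assignment used for
#' normalized crossover frequency (NCF) calculations. Positions increase
#' telomere to centromere; all distances are plain position differences.
#'
#' @param markers A data frame with columns `marker_id`, `rs_id`,
#'   `position_bp`, `kind` (`"SNP"` or `"DIP"`), `amplicon_id`, and
#'   `subregion_id` (integer or `NA`). Rows are sorted by `position_bp` on
#'   construction.
#' @return An object of class `marker_map`: the sorted marker data frame
#'   with a `subregions` attribute, a data frame of
#'   `(subregion_id, end_bp)` where `end_bp` is the centromeric-most
#'   (maximum) marker position of that sub-region.
#' @details Validation enforces: strictly increasing unique positions
#'   (duplicates are an error naming both markers, never silently
#'   reordered); known `kind` tokens; markers of one amplicon forming a
#'   contiguous run in position order; sub-regions forming contiguous,
#'   ordered blocks.
#' @seealso [read_marker_map()], [subregion_table()]
#' @export
marker_map <- function(markers) {
  required <- c("marker_id", "rs_id", "position_bp", "kind", "amplicon_id",
                "subregion_id")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  markers <- as.data.frame(markers)[required]
  markers$marker_id <- as.character(markers$marker_id)
  markers$rs_id <- as.character(markers$rs_id)
  markers$position_bp <- as.integer(markers$position_bp)
  markers$kind <- as.character(markers$kind)
  markers$amplicon_id <- as.character(markers$amplicon_id)
  markers$subregion_id <- suppressWarnings(as.integer(markers$subregion_id))

  if (nrow(markers) == 0L) stop("marker map must contain at least one marker")
  if (anyNA(markers$position_bp) || any(markers$position_bp <= 0L)) {
    stop("position_bp must be a positive integer for every marker")
  }
  bad_kind <- setdiff(unique(markers$kind), c("SNP", "DIP"))
  if (length(bad_kind) > 0L) {
    stop("unknown marker kind token(s): ", paste(bad_kind, collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  }
  dup <- duplicated(markers$position_bp)
  if (any(dup)) {
    pos <- markers$position_bp[dup][1L]
    ids <- markers$marker_id[markers$position_bp == pos]
    stop("duplicate position ", pos, " shared by markers: ",
         paste(ids, collapse = ", "))
  }
  markers <- markers[order(markers$position_bp), , drop = FALSE]
  rownames(markers) <- NULL

  # amplicons must be contiguous runs once sorted by position
  amp_runs <- rle(markers$amplicon_id)$values
  if (anyDuplicated(amp_runs)) {
    stop("amplicon(s) not contiguous in position order: ",
         paste(unique(amp_runs[duplicated(amp_runs)]), collapse = ", "))
  }

  sr <- markers$subregion_id
  if (any(!is.na(sr))) {
    sr_runs <- rle(sr[!is.na(sr)])$values
    if (anyDuplicated(sr_runs)) {
      stop("subregion(s) not contiguous in position order: ",
           paste(unique(sr_runs[duplicated(sr_runs)]), collapse = ", "))
    }
    if (is.unsorted(sr_runs)) {
      stop("subregion ids must increase telomere to centromere")
    }
    ends <- tapply(markers$position_bp[!is.na(sr)], sr[!is.na(sr)], max)
    subregions <- data.frame(
      subregion_id = as.integer(names(ends)),
      end_bp = as.integer(ends)
    )
    subregions <- subregions[order(subregions$subregion_id), , drop = FALSE]
    rownames(subregions) <- NULL
  } else {
    subregions <- data.frame(subregion_id = integer(0), end_bp = integer(0))
  }

  structure(markers, subregions = subregions,
            class = c("marker_map", "data.frame"))
}

#' Read a marker map from a tab-separated file
#'
#' Expects a header with columns `marker_id`, `rs_id`, `position_bp`,
#' `kind`, `amplicon_id`, `subregion_id`. Empty `rs_id`/`subregion_id`
#' cells (or `"."`) are treated as absent.
#'
#' @param path Path to the TSV file.
#' @return A [marker_map()] object.
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  tab$rs_id[tab$rs_id %in% c("", ".")] <- NA_character_
  tab$subregion_id[tab$subregion_id %in% c("", ".")] <- NA_character_
  tab$position_bp <- as.integer(tab$position_bp)
  marker_map(tab)
}

#' Write a marker map to a tab-separated file
#'
#' @param map A [marker_map()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  out <- as.data.frame(map)
  out$rs_id[is.na(out$rs_id)] <- "."
  out$subregion_id <- ifelse(is.na(out$subregion_id), ".",
                             as.character(out$subregion_id))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Sub-region boundary table of a marker map
#'
#' @param map A [marker_map()] object.
#' @return Data frame with columns `subregion_id` and `end_bp`, the
#'   centromeric-most analyzed position of each sub-region, ordered
#'   telomere to centromere.
#' @export
subregion_table <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  attr(map, "subregions")
}

#' @export
print.marker_map <- function(x, ...) {
  sr <- attr(x, "subregions")
  cat(sprintf("marker_map: %d markers, %d amplicons, %d sub-regions, span %d-%d bp\n",
              nrow(x), length(unique(x$amplicon_id)), nrow(sr),
              min(x$position_bp), max(x$position_bp)))
  invisible(x)
}
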