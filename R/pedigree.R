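#' Construct a pedigree
#'
#' @param subjects Data frame with columns `family_id`, `subject_id`,
#'   `father_id`, `mother_id`; `NA` parent means founder.
#' @return A `pedigree` object (validated data frame).
#' @details Validation: subject ids unique, parent references resolve
#'   within the same family, both parents present or both absent per
#'   subject is not required, and the parent graph is acyclic.
#' @export
pedigree <- function(subjects) {
  required <- c("family_id", "subject_id", "father_id", "mother_id")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0L) {
    stop("pedigree lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  subjects <- as.data.frame(subjects)[required]
  for (cc in required) subjects[[cc]] <- as.character(subjects[[cc]])
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  for (fam in unique(subjects$family_id)) {
    fs <- subjects[subjects$family_id == fam, , drop = FALSE]
    parents <- c(fs$father_id, fs$mother_id)
    parents <- parents[!is.na(parents)]
    unresolved <- setdiff(parents, fs$subject_id)
    if (length(unresolved) > 0L) {
      stop("family ", fam, ": parent(s) not present as subjects: ",
           paste(unique(unresolved), collapse = ", "))
    }
    # cycle check by iterative founder stripping
    remaining <- fs
    repeat {
      is_founder <- (is.na(remaining$father_id) |
                       !remaining$father_id %in% remaining$subject_id) &
                    (is.na(remaining$mother_id) |
                       !remaining$mother_id %in% remaining$subject_id)
      if (all(is_founder)) break
      if (!any(is_founder)) {
        stop("family ", fam, ": cyclic parentage among subjects: ",
             paste(remaining$subject_id, collapse = ", "))
      }
      remaining <- remaining[!is_founder, , drop = FALSE]
      if (nrow(remaining) == 0L) break
    }
  }
  rownames(subjects) <- NULL
  structure(subjects, class = c("pedigree", "data.frame"))
}

#' Founders of a pedigree
#' @param ped A [pedigree()].
#' @return Character vector of subject ids with no recorded parents.
#' @export
pedigree_founders <- function(ped) {
  ped$subject_id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

#' Construct a genotype table
#'
#' Unphased genotypes: an unordered pair of allele calls per subject per
#' marker. Pairs are stored in two matrices but all comparisons treat the
#' pair as unordered; either or both calls may be missing (`NA`).
#'
#' @param a1,a2 Character matrices (subjects x markers), `NA` = missing.
#' @param map A [marker_map()] the columns are aligned to.
#' @param subject_id Character vector of row identifiers.
#' @return A `genotype_table`: list with `a1`, `a2`, `subject_id`.
#' @export
genotype_table <- function(a1, a2, map, subject_id = rownames(a1)) {
  stopifnot(inherits(map, "marker_map"))
  a1 <- as.matrix(a1); mode(a1) <- "character"
  a2 <- as.matrix(a2); mode(a2) <- "character"
  if (!all(dim(a1) == dim(a2))) stop("allele matrices differ in shape")
  if (ncol(a1) != nrow(map)) {
    stop("genotype table has ", ncol(a1), " marker columns but map has ",
         nrow(map))
  }
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject_id in genotypes")
  dimnames(a1) <- dimnames(a2) <- list(subject_id, map$marker_id)
  structure(list(a1 = a1, a2 = a2, subject_id = subject_id),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d subjects x %d markers\n",
              nrow(x$a1), ncol(x$a1)))
  invisible(x)
}

#' Test unordered genotype-pair equality
#'
#' @param p1,p2 Length-2 character vectors (alleles, `NA` = missing).
#' @return `TRUE` when the two pairs contain the same multiset of calls.
#' @export
genotype_pair_equal <- function(p1, p2) {
  key <- function(p) paste(sort(as.character(p), na.last = TRUE), collapse = "/")
  identical(key(p1), key(p2))
}

#' Read a PED-like pedigree + genotype file
#'
#' Whitespace-separated rows: `family_id subject_id father_id mother_id`
#' followed by two allele tokens per marker in map order. A parent id of
#' `"0"` means founder; an allele token of `"0"` means missing.
#'
#' @param path Path to the PED-like file.
#' @param map A [marker_map()] defining marker order (the file must carry
#'   `2 * nrow(map)` allele tokens per row).
#' @return List with elements `pedigree` (a [pedigree()]) and `genotypes`
#'   (a [genotype_table()]).
#' @export
read_pedigree_genotypes <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_mark <- nrow(map)
  expect_len <- 4L + 2L * n_mark
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != expect_len) {
      stop("line ", i, ": expected ", expect_len, " fields, found ",
           length(fields[[i]]))
    }
  }
  m <- do.call(rbind, fields)
  ped <- data.frame(family_id = m[, 1L], subject_id = m[, 2L],
                    father_id = m[, 3L], mother_id = m[, 4L],
                    stringsAsFactors = FALSE)
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  geno <- m[, -(1:4), drop = FALSE]
  geno[geno == "0"] <- NA_character_
  a1 <- geno[, seq(1L, 2L * n_mark, by = 2L), drop = FALSE]
  a2 <- geno[, seq(2L, 2L * n_mark, by = 2L), drop = FALSE]
  rownames(a1) <- rownames(a2) <- ped$subject_id
  list(pedigree = pedigree(ped),
       genotypes = genotype_table(a1, a2, map, subject_id = ped$subject_id))
}

#' Write a PED-like pedigree + genotype file
#'
#' Inverse of [read_pedigree_genotypes()]; missing parents and missing
#' alleles are written as `"0"`.
#'
#' @param ped A [pedigree()].
#' @param geno A [genotype_table()] covering every pedigree subject.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree_genotypes <- function(ped, geno, path) {
  stopifnot(inherits(ped, "pedigree"), inherits(geno, "genotype_table"))
  idx <- match(ped$subject_id, geno$subject_id)
  if (anyNA(idx)) stop("genotype table lacks subject(s): ",
                       paste(ped$subject_id[is.na(idx)], collapse = ", "))
  n_mark <- ncol(geno$a1)
  inter <- matrix(NA_character_, nrow = nrow(ped), ncol = 2L * n_mark)
  inter[, seq(1L, 2L * n_mark, by = 2L)] <- geno$a1[idx, , drop = FALSE]
  inter[, seq(2L, 2L * n_mark, by = 2L)] <- geno$a2[idx, , drop = FALSE]
  inter[is.na(inter)] <- "0"
  lead <- cbind(ped$family_id, ped$subject_id,
                ifelse(is.na(ped$father_id), "0", ped$father_id),
                ifelse(is.na(ped$mother_id), "0", ped$mother_id))
  writeLines(apply(cbind(lead, inter), 1L, paste, collapse = "\t"), path)
  invisible(path)
}
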