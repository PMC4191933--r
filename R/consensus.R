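#' Define a CEH group by required core-marker alleles
#'
#' A conserved extended haplotype (CEH) group is keyed by the alleles a
#' haplotype must carry at designated core markers — the role played in
#' practice by HLA and complotype typing of the core MHC region.
#'
#' @param group_id Group label (e.g. `"B8,DR3"`).
#' @param core Named character vector: names are core marker ids, values
#'   the required allele tokens. At least one requirement.
#' @return A `ceh_group_spec` object.
#' @export
ceh_group_spec <- function(group_id, core) {
  if (length(core) < 1L) stop("group spec needs at least one core requirement")
  if (is.null(names(core)) || any(!nzchar(names(core)))) {
    stop("core requirements must be named by marker_id")
  }
  structure(list(group_id = as.character(group_id),
                 core = vapply(core, as.character, character(1))),
            class = "ceh_group_spec")
}

#' Assign haplotypes to CEH groups by core-marker alleles
#'
#' A haplotype joins a group iff it carries every required core allele of
#' that group's spec. Haplotypes matching no spec stay unassigned; a
#' haplotype with a missing call at a required marker is unassigned and
#' flagged untypable. Specs must partition the cohort: a haplotype
#' matching more than one spec is a configuration error.
#'
#' @param haps A [haplotype_set()].
#' @param specs List of [ceh_group_spec()] objects.
#' @param map The [marker_map()] the haplotypes are aligned to.
#' @return The `haplotype_set` with `info$group_id` filled in and an added
#'   logical column `info$untypable`.
#' @export
assign_groups <- function(haps, specs, map) {
  stopifnot(inherits(haps, "haplotype_set"), inherits(map, "marker_map"))
  if (inherits(specs, "ceh_group_spec")) specs <- list(specs)
  n <- n_haplotypes(haps)
  match_mat <- matrix(FALSE, nrow = n, ncol = length(specs))
  untypable <- rep(FALSE, n)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    idx <- match(names(sp$core), map$marker_id)
    if (anyNA(idx)) {
      stop("spec ", sp$group_id, ": core marker(s) not in map: ",
           paste(names(sp$core)[is.na(idx)], collapse = ", "))
    }
    sub <- haps$alleles[, idx, drop = FALSE]
    has_na <- rowSums(is.na(sub)) > 0L
    ok <- rowSums(sub == rep(sp$core, each = n), na.rm = TRUE) ==
      length(sp$core) & !has_na
    match_mat[, k] <- ok
    untypable <- untypable | (has_na & !ok)
  }
  multi <- rowSums(match_mat) > 1L
  if (any(multi)) {
    i <- which(multi)[1L]
    ids <- vapply(specs[match_mat[i, ]], function(s) s$group_id, character(1))
    stop("overlapping group specs (must partition): haplotype ",
         haps$info$haplotype_id[i], " matches ", paste(ids, collapse = " and "))
  }
  group <- rep(NA_character_, n)
  for (k in seq_along(specs)) group[match_mat[, k]] <- specs[[k]]$group_id
  haps$info$group_id <- group
  haps$info$untypable <- untypable & is.na(group)
  haps
}

# Modal allele among non-missing calls; detects ties and empty columns.
modal_allele <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) {
    return(list(allele = NA_character_, status = "no_data",
                tied = character(0)))
  }
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) {
    tied <- names(tab)[tab == tab[1L]]
    return(list(allele = NA_character_, status = "tie", tied = sort(tied)))
  }
  list(allele = names(tab)[1L], status = "defined", tied = character(0))
}

#' Compute the dominant (consensus) sequence of a CEH group
#'
#' Sweeping telomere to centromere from the anchor marker, the dominant
#' allele at each marker is the modal allele among retained members with
#' non-missing calls. A retained member deviates where its non-missing
#' allele differs from the dominant allele. A deviation is *isolated* —
#' private mutation or microvariation, not loss of conservation — iff the
#' member matches the dominant allele at its nearest non-missing,
#' dominant-defined markers on each side (`isolation_window` of them,
#' default 1; runs of two or more deviating markers are therefore always
#' non-isolated). An isolated deviation keeps the member retained; the
#' first non-isolated deviation removes it from the retained set at that
#' marker and for all markers centromeric of it (members are never
#' re-admitted). Missing calls never remove a member: unsequenced
#' intervals are bridged under the assumption of sequence identity. A
#' modal tie among retained members records a co-dominant split; the
#' dominant allele is undefined there and the tied continuations are
#' tracked in `co_dominant`.
#'
#' Because the dominant allele and the retained set define each other, the
#' computation iterates modal-allele and retained-set updates to a fixed
#' point (the first pass uses all members; convergence is typically
#' immediate).
#'
#' @param group_haps A [haplotype_set()] containing the members of one
#'   group.
#' @param map The [marker_map()].
#' @param anchor Map index of the telomeric anchor marker (default 1);
#'   markers telomeric of the anchor are ignored.
#' @param group_id Group label; defaults to the members' common
#'   `group_id` when present.
#' @param isolation_window Number of flanking non-missing markers a
#'   deviating member must match on each side to count as isolated.
#' @return A `dominant_sequence` object: list with `group_id`,
#'   `anchor` (map index), `marker_idx` (map indices analyzed),
#'   `position_bp`, `dominant` (allele or `NA` when undefined), `status`
#'   (`"defined"`, `"tie"`, `"no_data"` per marker), `retained` (logical
#'   members x markers matrix), `retained_count`, `support` (retained
#'   members with non-missing calls per marker), `deviations` (data frame
#'   of every deviation with its isolated flag), `co_dominant` (list of
#'   tie records), `first_dev` (per member, map index of its first
#'   non-isolated deviation or `NA`), `member_ids`, `group_size`.
#' @export
compute_dominant_sequence <- function(group_haps, map, anchor = 1L,
                                      group_id = NULL,
                                      isolation_window = 1L) {
  stopifnot(inherits(group_haps, "haplotype_set"), inherits(map, "marker_map"))
  n <- n_haplotypes(group_haps)
  if (n == 0L) stop("cannot compute a dominant sequence for an empty group")
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > nrow(map)) stop("anchor outside marker map")
  if (is.null(group_id)) {
    g <- unique(stats::na.omit(group_haps$info$group_id))
    group_id <- if (length(g) == 1L) g else NA_character_
  }
  idx <- seq.int(anchor, nrow(map))
  A <- group_haps$alleles[, idx, drop = FALSE]
  L <- length(idx)

  retained <- matrix(TRUE, nrow = n, ncol = L)
  first_dev_local <- rep(NA_integer_, n)
  dominant <- rep(NA_character_, L)
  status <- rep("no_data", L)

  for (iter in seq_len(20L)) {
    ties <- vector("list", L)
    for (j in seq_len(L)) {
      m <- modal_allele(A[retained[, j], j])
      dominant[j] <- m$allele
      status[j] <- m$status
      ties[[j]] <- m$tied
    }
    new_first <- vapply(seq_len(n), function(i) {
      first_nonisolated_deviation(A[i, ], dominant, status, isolation_window)
    }, integer(1))
    new_retained <- matrix(TRUE, nrow = n, ncol = L)
    for (i in seq_len(n)) {
      if (!is.na(new_first[i]) && new_first[i] <= L) {
        new_retained[i, seq.int(new_first[i], L)] <- FALSE
      }
    }
    converged <- identical(new_retained, retained) &&
      identical(new_first, first_dev_local)
    retained <- new_retained
    first_dev_local <- new_first
    if (converged && iter > 1L) break
  }

  # final dominant under the converged retained set
  co_dominant <- list()
  for (j in seq_len(L)) {
    m <- modal_allele(A[retained[, j], j])
    dominant[j] <- m$allele
    status[j] <- m$status
    if (m$status == "tie") {
      carriers <- lapply(m$tied, function(al) {
        group_haps$info$haplotype_id[retained[, j] & !is.na(A[, j]) &
                                       A[, j] == al]
      })
      names(carriers) <- m$tied
      co_dominant[[length(co_dominant) + 1L]] <-
        list(marker_idx = idx[j], position_bp = map$position_bp[idx[j]],
             alleles = m$tied, carriers = carriers)
    }
  }

  # full deviation log (isolated and not) against the final dominant
  dev_rows <- list()
  for (i in seq_len(n)) {
    devs <- deviation_scan(A[i, ], dominant, status, isolation_window)
    if (length(devs$at) > 0L) {
      dev_rows[[length(dev_rows) + 1L]] <- data.frame(
        haplotype_id = group_haps$info$haplotype_id[i],
        marker_idx = idx[devs$at],
        position_bp = map$position_bp[idx[devs$at]],
        allele = A[i, devs$at],
        isolated = devs$isolated,
        stringsAsFactors = FALSE)
    }
  }
  deviations <- if (length(dev_rows) > 0L) do.call(rbind, dev_rows) else
    data.frame(haplotype_id = character(0), marker_idx = integer(0),
               position_bp = integer(0), allele = character(0),
               isolated = logical(0), stringsAsFactors = FALSE)
  rownames(deviations) <- NULL

  first_dev <- ifelse(is.na(first_dev_local), NA_integer_,
                      idx[first_dev_local])
  names(first_dev) <- group_haps$info$haplotype_id
  rownames(retained) <- group_haps$info$haplotype_id

  structure(list(group_id = group_id, anchor = anchor, marker_idx = idx,
                 position_bp = map$position_bp[idx],
                 dominant = dominant, status = status,
                 retained = retained,
                 retained_count = as.integer(colSums(retained)),
                 support = vapply(seq_len(L), function(j)
                   sum(retained[, j] & !is.na(A[, j])), integer(1)),
                 deviations = deviations, co_dominant = co_dominant,
                 first_dev = first_dev,
                 member_ids = group_haps$info$haplotype_id,
                 group_size = n),
            class = "dominant_sequence")
}

# Local index of a member's first non-isolated deviation, NA if none.
first_nonisolated_deviation <- function(calls, dominant, status, window) {
  devs <- deviation_scan(calls, dominant, status, window)
  hit <- devs$at[!devs$isolated]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# All deviations of one member against the dominant vector, with the
# isolated flag. Comparable markers: member call non-missing and dominant
# defined. Isolation requires matching the dominant at the nearest
# `window` comparable markers on each side (sides with fewer comparable
# markers impose no constraint).
deviation_scan <- function(calls, dominant, status, window) {
  comparable <- which(!is.na(calls) & status == "defined")
  if (length(comparable) == 0L) {
    return(list(at = integer(0), isolated = logical(0)))
  }
  match_flag <- calls[comparable] == dominant[comparable]
  dev_pos <- which(!match_flag)
  if (length(dev_pos) == 0L) {
    return(list(at = integer(0), isolated = logical(0)))
  }
  isolated <- vapply(dev_pos, function(k) {
    left <- seq_len(k - 1L)
    left <- utils::tail(left, window)
    right <- seq.int(k + 1L, length.out = max(0L, length(comparable) - k))
    right <- utils::head(right, window)
    all(match_flag[left]) && all(match_flag[right])
  }, logical(1))
  list(at = comparable[dev_pos], isolated = isolated)
}

#' @export
print.dominant_sequence <- function(x, ...) {
  cat(sprintf(
    "dominant_sequence [%s]: %d members, %d markers from anchor, final retained %d (%.1f%%), %d co-dominant split(s)\n",
    ifelse(is.na(x$group_id), "?", x$group_id), x$group_size,
    length(x$marker_idx), utils::tail(x$retained_count, 1L),
    100 * utils::tail(x$retained_count, 1L) / x$group_size,
    length(x$co_dominant)))
  invisible(x)
}

#' Sequence-fixity curve of a CEH group
#'
#' Fixity at a position is the fraction of the group's haplotypes still
#' identical to the dominant sequence (isolated private variation
#' tolerated) from the telomeric anchor through that position. The
#' denominator is the full group membership, including members that have
#' already crossed over, so the curve is non-increasing from 1.
#'
#' @param dom A [compute_dominant_sequence()] result.
#' @param group_size Denominator; defaults to the group size recorded in
#'   `dom`.
#' @return A `fixity_curve`: data frame with `group_id`, `position_bp`,
#'   `retained_count`, `fraction`, one row per analyzed marker.
#' @export
compute_fixity_curve <- function(dom, group_size = dom$group_size) {
  stopifnot(inherits(dom, "dominant_sequence"))
  out <- data.frame(group_id = dom$group_id,
                    position_bp = dom$position_bp,
                    retained_count = as.integer(dom$retained_count),
                    fraction = dom$retained_count / group_size,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fixity_curve", "data.frame"))
}
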