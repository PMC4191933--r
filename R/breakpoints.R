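#' Localize each member's loss of the dominant sequence to an interval
#'
#' A haplotype's break point is bracketed by the last non-missing marker
#' at which it matched the dominant allele and the first non-isolated
#' deviation; missing markers in between widen the interval (the break
#' point "occurred but could not be precisely localized"). Members that
#' carry the dominant sequence through the final analyzed marker are
#' `retained_through_end`.
#'
#' @param group_haps The [haplotype_set()] the dominant sequence was
#'   computed from (same member order).
#' @param dom A [compute_dominant_sequence()] result.
#' @param map The [marker_map()].
#' @param anchor_bp Boundary position assigned as `last_match_pos` to a
#'   member deviating at the anchor marker itself, the convention being
#'   that all group members carry the dominant sequence at the centromeric
#'   end of the core region preceding the map. Defaults to one bp
#'   telomeric of the anchor marker.
#' @return A `breakpoint_calls` data frame: `haplotype_id`, `group_id`,
#'   `status` (`"crossed_over"` / `"retained_through_end"`),
#'   `last_match_pos`, `first_mismatch_pos`, `interval_width_bp`.
#' @export
call_breakpoints <- function(group_haps, dom, map,
                             anchor_bp = map$position_bp[dom$anchor] - 1L) {
  stopifnot(inherits(group_haps, "haplotype_set"),
            inherits(dom, "dominant_sequence"), inherits(map, "marker_map"))
  if (!identical(group_haps$info$haplotype_id, dom$member_ids)) {
    stop("haplotype set does not match the dominant sequence's members")
  }
  n <- n_haplotypes(group_haps)
  out <- data.frame(haplotype_id = dom$member_ids,
                    group_id = dom$group_id,
                    status = "retained_through_end",
                    last_match_pos = NA_integer_,
                    first_mismatch_pos = NA_integer_,
                    interval_width_bp = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- dom$first_dev[i]          # map index of first non-isolated deviation
    if (is.na(f)) next
    out$status[i] <- "crossed_over"
    out$first_mismatch_pos[i] <- map$position_bp[f]
    local_f <- match(f, dom$marker_idx)
    calls <- group_haps$alleles[i, dom$marker_idx, drop = TRUE]
    before <- seq_len(local_f - 1L)
    ok <- before[!is.na(calls[before]) & dom$status[before] == "defined" &
                   calls[before] == dom$dominant[before]]
    out$last_match_pos[i] <- if (length(ok) > 0L) {
      dom$position_bp[max(ok)]
    } else as.integer(anchor_bp)
    out$interval_width_bp[i] <- out$first_mismatch_pos[i] - out$last_match_pos[i]
  }
  structure(out, class = c("breakpoint_calls", "data.frame"))
}

#' How far an external reference haplotype represents a CEH group
#'
#' Scans telomere to centromere: the reference represents the group while
#' it carries the dominant allele, tolerating isolated reference
#' mismatches (same isolation rule as the dominant-sequence sweep; a
#' tolerated mismatch is a candidate private mutation of the reference).
#' Representation ends at the first non-isolated mismatch, or at a
#' co-dominant split whose tied continuations the reference matches
#' neither of.
#'
#' @param reference A [haplotype_set()] with one row (or a named row
#'   selected via `reference_id`), aligned to `map`.
#' @param dom A [compute_dominant_sequence()] result.
#' @param map The [marker_map()].
#' @param isolation_window As in [compute_dominant_sequence()].
#' @return A `representation_extent` list: `reference_id`, `group_id`,
#'   `whole_map` (logical), `end_interval` = `c(last_represented_pos,
#'   first_nonrepresented_pos)` or `NULL`, `private_mismatches_tolerated`
#'   (map marker indices), `status` (`"resolved"`/`"unresolvable"`).
#' @export
representation_extent <- function(reference, dom, map, isolation_window = 1L) {
  stopifnot(inherits(reference, "haplotype_set"),
            inherits(dom, "dominant_sequence"), inherits(map, "marker_map"))
  if (n_haplotypes(reference) != 1L) {
    stop("supply exactly one reference haplotype")
  }
  ref_id <- reference$info$haplotype_id[1L]
  calls <- reference$alleles[1L, dom$marker_idx, drop = TRUE]

  analyzed <- dom$status != "no_data"
  if (sum(analyzed) > 0L && mean(is.na(calls[analyzed])) > 0.5) {
    return(structure(list(reference_id = ref_id, group_id = dom$group_id,
                          whole_map = FALSE, end_interval = NULL,
                          private_mismatches_tolerated = integer(0),
                          status = "unresolvable"),
                     class = "representation_extent"))
  }

  devs <- deviation_scan(calls, dom$dominant, dom$status, isolation_window)
  end_local <- NA_integer_
  hit <- devs$at[!devs$isolated]
  if (length(hit) > 0L) end_local <- hit[1L]

  # co-dominant split the reference matches neither continuation of
  tie_local <- which(dom$status == "tie")
  for (j in tie_local) {
    if (!is.na(end_local) && j >= end_local) break
    tied <- dom$co_dominant[[match(dom$marker_idx[j],
                                   vapply(dom$co_dominant, `[[`, integer(1),
                                          "marker_idx"))]]$alleles
    if (!is.na(calls[j]) && !(calls[j] %in% tied)) {
      end_local <- j
      break
    }
  }

  tolerated_local <- devs$at[devs$isolated]
  if (!is.na(end_local)) {
    tolerated_local <- tolerated_local[tolerated_local < end_local]
  }
  if (is.na(end_local)) {
    res <- list(reference_id = ref_id, group_id = dom$group_id,
                whole_map = TRUE, end_interval = NULL,
                private_mismatches_tolerated = dom$marker_idx[tolerated_local],
                status = "resolved")
  } else {
    comparable <- which(!is.na(calls) & dom$status == "defined" &
                          calls == dom$dominant)
    comparable <- comparable[comparable < end_local]
    last_rep <- if (length(comparable) > 0L) {
      dom$position_bp[max(comparable)]
    } else NA_integer_
    res <- list(reference_id = ref_id, group_id = dom$group_id,
                whole_map = FALSE,
                end_interval = c(last_represented_pos = last_rep,
                                 first_nonrepresented_pos =
                                   dom$position_bp[end_local]),
                private_mismatches_tolerated = dom$marker_idx[tolerated_local],
                status = "resolved")
  }
  structure(res, class = "representation_extent")
}

#' @export
print.representation_extent <- function(x, ...) {
  if (x$status == "unresolvable") {
    cat(sprintf("representation_extent: %s vs %s — unresolvable (too much missing data)\n",
                x$reference_id, x$group_id))
  } else if (x$whole_map) {
    cat(sprintf("representation_extent: %s represents %s through the whole map (%d tolerated private mismatch(es))\n",
                x$reference_id, x$group_id,
                length(x$private_mismatches_tolerated)))
  } else {
    cat(sprintf("representation_extent: %s represents %s up to (%s, %s] bp (%d tolerated)\n",
                x$reference_id, x$group_id,
                format(x$end_interval[1L]), format(x$end_interval[2L]),
                length(x$private_mismatches_tolerated)))
  }
  invisible(x)
}

#' Find regional tag markers of a CEH group
#'
#' A (marker, allele) pair tags a group iff every retained group member
#' with a non-missing call carries the allele and no haplotype outside the
#' retained set — including crossed-over members of the same group —
#' carries it (non-missing calls only). The retained set at each marker
#' comes from the dominant-sequence sweep.
#'
#' @param dom A [compute_dominant_sequence()] result for the group.
#' @param cohort A [haplotype_set()] with every haplotype under study
#'   (group members and all others).
#' @param map The [marker_map()].
#' @return Data frame `marker_idx`, `marker_id`, `position_bp`, `allele`,
#'   `n_carriers`, `n_noncarriers`; zero rows when no marker qualifies.
#' @export
find_tag_markers <- function(dom, cohort, map) {
  stopifnot(inherits(dom, "dominant_sequence"),
            inherits(cohort, "haplotype_set"), inherits(map, "marker_map"))
  rows <- list()
  for (jl in seq_along(dom$marker_idx)) {
    if (dom$status[jl] != "defined") next
    j <- dom$marker_idx[jl]
    retained_ids <- dom$member_ids[dom$retained[, jl]]
    in_ret <- cohort$info$haplotype_id %in% retained_ids
    allele <- dom$dominant[jl]
    inside <- cohort$alleles[in_ret, j]
    # every retained member with a call must carry the dominant allele
    if (!all(inside == allele, na.rm = TRUE)) next
    if (all(is.na(inside))) next
    outside <- cohort$alleles[!in_ret, j]
    if (any(outside == allele, na.rm = TRUE)) next
    if (sum(!is.na(outside)) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_idx = j, marker_id = map$marker_id[j],
      position_bp = map$position_bp[j], allele = allele,
      n_carriers = sum(!is.na(inside)),
      n_noncarriers = sum(!is.na(outside)), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(marker_idx = integer(0), marker_id = character(0),
               position_bp = integer(0), allele = character(0),
               n_carriers = integer(0), n_noncarriers = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Find private variants within a group's conserved sequence
#'
#' Reports isolated deviations (from the dominant-sequence sweep) whose
#' allele is carried by exactly one haplotype in the whole cohort at that
#' marker — the signature of a private mutation on an otherwise conserved
#' haplotype.
#'
#' @param dom A [compute_dominant_sequence()] result.
#' @param cohort A [haplotype_set()] with every haplotype under study.
#' @param map The [marker_map()].
#' @return Data frame `haplotype_id`, `marker_idx`, `marker_id`,
#'   `position_bp`, `allele`.
#' @export
find_private_variants <- function(dom, cohort, map) {
  stopifnot(inherits(dom, "dominant_sequence"),
            inherits(cohort, "haplotype_set"), inherits(map, "marker_map"))
  iso <- dom$deviations[dom$deviations$isolated, , drop = FALSE]
  keep <- logical(nrow(iso))
  for (r in seq_len(nrow(iso))) {
    j <- iso$marker_idx[r]
    carriers <- sum(cohort$alleles[, j] == iso$allele[r], na.rm = TRUE)
    keep[r] <- carriers == 1L
  }
  out <- iso[keep, c("haplotype_id", "marker_idx", "position_bp", "allele"),
             drop = FALSE]
  out$marker_id <- map$marker_id[out$marker_idx]
  rownames(out) <- NULL
  out[, c("haplotype_id", "marker_idx", "marker_id", "position_bp", "allele")]
}
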