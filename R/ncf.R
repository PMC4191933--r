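#' Normalized crossover frequency of a single sub-region
#'
#' NCF is the fraction of the remaining dominant-sequence haplotypes of a
#' CEH that cross over to a non-dominant sequence within a sub-region,
#' normalized to a 1 Mb unit distance so that sub-regions of different
#' sizes can be compared:
#'
#' `NCF = (crossovers / total remaining haplotypes) * (1e6 / distance covered)`
#'
#' Units: crossovers per remaining haplotype per Mb.
#'
#' @param crossovers Number of haplotypes losing the dominant sequence
#'   within the sub-region.
#' @param remaining Number of haplotypes still carrying the dominant
#'   sequence throughout the region immediately telomeric.
#' @param distance_bp Distance covered by the sub-region, in bases.
#' @return The NCF value (full precision; display convention is one
#'   decimal).
#' @examples
#' ncf_value(3, 16, 21096)  # 8.888...; printed as 8.9
#' @export
ncf_value <- function(crossovers, remaining, distance_bp) {
  if (any(remaining <= 0 & crossovers > 0)) {
    stop("impossible state: crossovers reported with no remaining haplotypes")
  }
  ifelse(remaining > 0, (crossovers / remaining) * (1e6 / distance_bp), 0)
}

#' Per-sub-region NCF table from breakpoint calls
#'
#' Walks the map's sub-regions telomere to centromere. A crossover is
#' assigned to sub-region `r` iff its `first_mismatch_pos` lies centromeric
#' to the prior sub-region's centromeric-most analyzed point and at or
#' telomeric to sub-region `r`'s centromeric-most point — so a crossover
#' deduced to have occurred between two analyzed regions falls in the
#' current (centromeric) one. The distance covered by `r` is the
#' difference of consecutive centromeric-most points (for the first
#' sub-region, measured from `anchor_bp`). The remaining-haplotype
#' denominator starts at the full group size: every member is assumed to
#' carry the dominant sequence at the anchor.
#'
#' @param breakpoints A [call_breakpoints()] result for one group.
#' @param map The [marker_map()]; must define sub-regions.
#' @param group_size Total members of the group (the `remaining` of the
#'   first sub-region).
#' @param anchor_bp Genomic position of the anchor point from which the
#'   first sub-region's distance is measured.
#' @return An `ncf_table` data frame: `group_id`, `subregion_id`,
#'   `start_bp`, `end_bp`, `distance_bp`, `crossovers`, `remaining`,
#'   `ncf` (full precision) and `ncf_display` (one decimal).
#' @export
compute_ncf <- function(breakpoints, map, group_size,
                        anchor_bp = min(map$position_bp) - 1L) {
  stopifnot(inherits(map, "marker_map"))
  sr <- subregion_table(map)
  if (nrow(sr) == 0L) stop("marker map defines no sub-regions")
  bounds <- c(as.integer(anchor_bp), sr$end_bp)
  if (is.unsorted(bounds, strictly = TRUE)) {
    stop("anchor_bp must be telomeric to every sub-region boundary")
  }
  xo <- breakpoints$first_mismatch_pos[breakpoints$status == "crossed_over"]
  if (any(xo <= anchor_bp | xo > sr$end_bp[nrow(sr)])) {
    stop("breakpoint position outside the map's sub-region span")
  }
  K <- nrow(sr)
  crossovers <- integer(K)
  for (p in xo) {
    r <- which(p > bounds[-length(bounds)] & p <= bounds[-1L])[1L]
    crossovers[r] <- crossovers[r] + 1L
  }
  remaining <- integer(K)
  remaining[1L] <- as.integer(group_size)
  if (K > 1L) {
    for (r in 2:K) remaining[r] <- remaining[r - 1L] - crossovers[r - 1L]
  }
  if (any(remaining == 0L & crossovers > 0L)) {
    stop("impossible state: crossovers in a sub-region entered by 0 haplotypes")
  }
  distance <- diff(bounds)
  ncf <- ncf_value(crossovers, remaining, distance)
  gid <- unique(breakpoints$group_id)
  out <- data.frame(group_id = if (length(gid) == 1L) gid else NA_character_,
                    subregion_id = sr$subregion_id,
                    start_bp = bounds[-length(bounds)],
                    end_bp = sr$end_bp,
                    distance_bp = as.integer(distance),
                    crossovers = crossovers,
                    remaining = remaining,
                    ncf = ncf,
                    ncf_display = round(ncf, 1L),
                    stringsAsFactors = FALSE)
  attr(out, "group_size") <- as.integer(group_size)
  attr(out, "anchor_bp") <- as.integer(anchor_bp)
  structure(out, class = c("ncf_table", "data.frame"))
}

#' Remaining-haplotype trajectory across sub-regions
#'
#' @param ncf_table A [compute_ncf()] result.
#' @return Integer vector of length `K + 1`: the remaining count entering
#'   each of the `K` sub-regions, then the count retained through the
#'   last one.
#' @export
remaining_trajectory <- function(ncf_table) {
  stopifnot(inherits(ncf_table, "ncf_table"))
  K <- nrow(ncf_table)
  c(ncf_table$remaining,
    ncf_table$remaining[K] - ncf_table$crossovers[K])
}

#' Plot NCF bars with fixity curves on a to-scale genomic axis
#'
#' The bar for each sub-region spans its genomic extent (width =
#' distance covered) with height = NCF, so the bar *area* is proportional
#' to the fraction of remaining haplotypes lost there
#' (`area = ncf * width / 1e6 = crossovers / remaining`); areas, not
#' heights, are the comparable quantity. Fixity curves are drawn in an
#' aligned upper panel.
#'
#' @param fixity_curves List of [compute_fixity_curve()] results (or one).
#' @param ncf_tables List of [compute_ncf()] results (or one).
#' @return A `ggplot` object.
#' @export
plot_ncf_fixity <- function(fixity_curves, ncf_tables) {
  if (inherits(fixity_curves, "fixity_curve")) fixity_curves <- list(fixity_curves)
  if (inherits(ncf_tables, "ncf_table")) ncf_tables <- list(ncf_tables)
  fx <- do.call(rbind, lapply(fixity_curves, as.data.frame))
  nc <- do.call(rbind, lapply(ncf_tables, as.data.frame))
  fx$panel <- "sequence fixity"
  nc$panel <- "NCF (crossovers / haplotype / Mb)"
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = nc,
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   ymin = 0, ymax = .data$ncf, fill = .data$group_id),
      alpha = 0.6, colour = "grey30") +
    ggplot2::geom_step(
      data = fx,
      ggplot2::aes(x = .data$position_bp / 1e6, y = .data$fraction,
                   colour = .data$group_id)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "chromosome 6 position (Mb, GRCh37)", y = NULL,
                  colour = "CEH group", fill = "CEH group") +
    ggplot2::theme_bw()
}

#' Write fixity and NCF reports to a directory
#'
#' Emits `fixity.tsv` and `ncf.tsv` (full-precision values plus the
#' one-decimal display column), bit-stable given identical inputs, and a
#' `ncf_fixity.pdf` figure from [plot_ncf_fixity()]. Empty inputs produce
#' header-only tables and no figure.
#'
#' @param fixity_curves List of [compute_fixity_curve()] results.
#' @param ncf_tables List of [compute_ncf()] results.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of paths written, invisibly.
#' @export
render_reports <- function(fixity_curves, ncf_tables, out_dir) {
  if (inherits(fixity_curves, "fixity_curve")) fixity_curves <- list(fixity_curves)
  if (inherits(ncf_tables, "ncf_table")) ncf_tables <- list(ncf_tables)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty_fx <- data.frame(group_id = character(0), position_bp = integer(0),
                         retained_count = integer(0), fraction = numeric(0))
  fx <- if (length(fixity_curves) > 0L) {
    do.call(rbind, lapply(fixity_curves, as.data.frame))
  } else empty_fx
  empty_nc <- data.frame(group_id = character(0), subregion_id = integer(0),
                         start_bp = integer(0), end_bp = integer(0),
                         distance_bp = integer(0), crossovers = integer(0),
                         remaining = integer(0), ncf = numeric(0),
                         ncf_display = numeric(0))
  nc <- if (length(ncf_tables) > 0L) {
    do.call(rbind, lapply(ncf_tables, as.data.frame))
  } else empty_nc
  fx_path <- file.path(out_dir, "fixity.tsv")
  nc_path <- file.path(out_dir, "ncf.tsv")
  utils::write.table(format(fx, digits = 15, trim = TRUE, scientific = FALSE),
                     fx_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(nc, digits = 15, trim = TRUE, scientific = FALSE),
                     nc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(fx_path, nc_path)
  if (nrow(fx) > 0L && nrow(nc) > 0L) {
    fig_path <- file.path(out_dir, "ncf_fixity.pdf")
    grDevices::pdf(fig_path, width = 9, height = 6)
    print(plot_ncf_fixity(fixity_curves, ncf_tables))
    grDevices::dev.off()
    paths <- c(paths, fig_path)
  }
  invisible(paths)
}
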