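make_example_group <- function() {
  map <- tiny_map()
  haps <- haps_from_strings(
    c(h1 = "ACGTAC", h2 = "ACGTAC", h3 = "ACGATG", h4 = "ACGTGC"),
    map, group_id = "G")
  dom <- compute_dominant_sequence(haps, map)
  list(map = map, haps = haps, dom = dom)
}

test_that("breakpoints bracket the first non-isolated deviation", {
  ex <- make_example_group()
  bp <- call_breakpoints(ex$haps, ex$dom, ex$map)
  h3 <- bp[bp$haplotype_id == "h3", ]
  expect_identical(h3$status, "crossed_over")
  expect_identical(h3$last_match_pos, as.integer(ex$map$position_bp[3]))
  expect_identical(h3$first_mismatch_pos, as.integer(ex$map$position_bp[4]))
  expect_identical(h3$interval_width_bp,
                   as.integer(diff(ex$map$position_bp[3:4])))
  # h4's isolated deviation is not a break point
  expect_identical(bp$status[bp$haplotype_id == "h4"], "retained_through_end")
  expect_true(all(is.na(bp$last_match_pos[bp$status == "retained_through_end"])))
})

test_that("missing markers widen the breakpoint interval", {
  map <- tiny_map()
  haps <- haps_from_strings(
    c(h1 = "ACGTAC", h2 = "ACGTAC", h3 = "ACGTAC", h4 = "ACGTTG"),
    map, group_id = "G")
  haps$alleles["h4", 4] <- NA   # gap just before the deviation run at 5,6
  dom <- compute_dominant_sequence(haps, map)
  bp <- call_breakpoints(haps, dom, map)
  h4 <- bp[bp$haplotype_id == "h4", ]
  expect_identical(h4$status, "crossed_over")
  expect_identical(h4$last_match_pos, as.integer(map$position_bp[3]))
  expect_identical(h4$first_mismatch_pos, as.integer(map$position_bp[5]))
})

test_that("a member deviating at the anchor gets the anchor boundary", {
  map <- tiny_map()
  haps <- haps_from_strings(
    c(h1 = "ACGTAC", h2 = "ACGTAC", h3 = "GTGTAC"), map, group_id = "G")
  dom <- compute_dominant_sequence(haps, map)
  bp <- call_breakpoints(haps, dom, map, anchor_bp = 999999L)
  h3 <- bp[bp$haplotype_id == "h3", ]
  expect_identical(h3$last_match_pos, 999999L)
  expect_identical(h3$first_mismatch_pos, as.integer(map$position_bp[1]))
})

test_that("retained-through-end count matches the final retained count", {
  cfg <- sim_config(n_markers = 80, groups = c(G1 = 25L), n_subregions = 4,
                    p_r = 0.15, mu = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  g <- subset_haplotypes(sim$truth_haps, !is.na(sim$truth_haps$info$group_id))
  dom <- compute_dominant_sequence(g, sim$map)
  bp <- call_breakpoints(g, dom, sim$map)
  expect_identical(sum(bp$status == "retained_through_end"),
                   as.integer(unname(utils::tail(dom$retained_count, 1))))
})

test_that("breakpoint intervals contain the planted crossover positions", {
  cfg <- sim_config(n_markers = 120, groups = c(G1 = 50L), n_subregions = 6,
                    p_r = 0.12, mu = 0, missing_rate = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  g <- subset_haplotypes(sim$truth_haps, !is.na(sim$truth_haps$info$group_id))
  dom <- compute_dominant_sequence(g, sim$map)
  bp <- call_breakpoints(g, dom, sim$map, anchor_bp = sim$truth$anchor_bp)
  truth <- sim$truth$haplotypes
  crossed <- which(!is.na(truth$xo_pos))
  expect_gt(length(crossed), 0L)
  for (i in crossed) {
    row <- bp[bp$haplotype_id == truth$haplotype_id[i], ]
    expect_identical(row$status, "crossed_over")
    expect_true(row$last_match_pos < truth$xo_pos[i] &&
                  truth$xo_pos[i] < row$first_mismatch_pos)
  }
})

test_that("a reference equal to the dominant sequence is represented whole-map", {
  ex <- make_example_group()
  ref <- haps_from_strings(c(REF = "ACGTAC"), ex$map)
  ref$info$source <- "reference"
  ext <- representation_extent(ref, ex$dom, ex$map)
  expect_true(ext$whole_map)
  expect_length(ext$private_mismatches_tolerated, 0L)
})

test_that("one isolated reference mismatch is tolerated as a private mutation", {
  ex <- make_example_group()
  ref <- haps_from_strings(c(REF = "ACTTAC"), ex$map)  # lone mismatch at m3
  ext <- representation_extent(ref, ex$dom, ex$map)
  expect_true(ext$whole_map)
  expect_identical(ext$private_mismatches_tolerated, 3L)
})

test_that("two consecutive mismatches end representation after the last match", {
  ex <- make_example_group()
  ref <- haps_from_strings(c(REF = "ACGTGT"), ex$map)  # mismatch at m5, m6
  ext <- representation_extent(ref, ex$dom, ex$map)
  expect_false(ext$whole_map)
  expect_identical(unname(ext$end_interval),
                   as.integer(ex$map$position_bp[4:5]))
})

test_that("a mostly missing reference is unresolvable", {
  ex <- make_example_group()
  ref <- haps_from_strings(c(REF = "ACGTAC"), ex$map)
  ref$alleles[1, 1:4] <- NA
  ext <- representation_extent(ref, ex$dom, ex$map)
  expect_identical(ext$status, "unresolvable")
})

test_that("tag markers split retained members from the rest of the cohort", {
  # a planted partition: 25 retained members carry G at one marker,
  # the other 133 cohort haplotypes carry T
  map <- tiny_map(positions = seq(1e6, by = 1e4, length.out = 4))
  members <- haps_from_strings(
    stats::setNames(rep("ACGT", 25), sprintf("mem%02d", 1:25)), map,
    group_id = "B8DR3")
  others <- haps_from_strings(
    stats::setNames(rep("ACTT", 133), sprintf("oth%03d", 1:133)), map)
  cohort <- haplotype_set(rbind(members$alleles, others$alleles), map,
                          haplotype_id = c(members$info$haplotype_id,
                                           others$info$haplotype_id))
  dom <- compute_dominant_sequence(members, map)
  tags <- find_tag_markers(dom, cohort, map)
  expect_identical(tags$marker_idx, 3L)
  expect_identical(tags$allele, "G")
  expect_identical(tags$n_carriers, 25L)
  expect_identical(tags$n_noncarriers, 133L)
})

test_that("cohort-wide alleles and outside carriers disqualify a tag", {
  map <- tiny_map(positions = seq(1e6, by = 1e4, length.out = 4))
  members <- haps_from_strings(c(m1 = "ACGT", m2 = "ACGT"), map,
                               group_id = "G")
  # outsider sharing the candidate allele at m3 -> no tag there; markers
  # 1, 2, 4 are cohort-wide constants -> no tag anywhere
  outsider <- haps_from_strings(c(o1 = "ACGT"), map)
  cohort <- haplotype_set(rbind(members$alleles, outsider$alleles), map,
                          haplotype_id = c("m1", "m2", "o1"))
  dom <- compute_dominant_sequence(members, map)
  expect_identical(nrow(find_tag_markers(dom, cohort, map)), 0L)
})

test_that("private variants are unique isolated alleles, shared ones excluded", {
  map <- tiny_map()
  haps <- haps_from_strings(
    c(h1 = "ACGTAC", h2 = "ACGTAC", h3 = "ACGTAC", h4 = "ACGTGC",
      h5 = "ACGAAC", h6 = "ACGAAC"),  # h5/h6 share the m4 minor allele
    map, group_id = "G")
  dom <- compute_dominant_sequence(haps, map)
  priv <- find_private_variants(dom, haps, map)
  expect_identical(priv$haplotype_id, "h4")
  expect_identical(priv$marker_idx, 5L)
  expect_identical(priv$allele, "G")
})

test_that("simulated private mutations on conserved segments are recovered", {
  cfg <- sim_config(n_markers = 120, groups = c(G1 = 40L), n_subregions = 4,
                    p_r = 0.08, mu = 0.004, missing_rate = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  g <- subset_haplotypes(sim$truth_haps, !is.na(sim$truth_haps$info$group_id))
  dom <- compute_dominant_sequence(g, sim$map)
  priv <- find_private_variants(dom, sim$truth_haps, sim$map)
  planted <- sim$truth$private_mutations
  expect_gt(nrow(planted), 0L)
  found <- paste(priv$haplotype_id, priv$marker_idx)
  want <- paste(planted$haplotype_id, planted$marker_idx)
  expect_true(all(want %in% found))
})
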