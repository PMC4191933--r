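test_that("a fully informative trio phases to the unique consistent founder set", {
  map <- tiny_map(positions = c(100, 200, 300))
  father <- rbind(c("A", "A"), c("C", "T"), c("G", "G"))
  mother <- rbind(c("A", "C"), c("C", "C"), c("G", "T"))
  child <- rbind(c("A", "A"), c("C", "C"), c("G", "G"))

  # brute-force oracle: the phase configuration is unique
  phases <- enumerate_trio_phases(father, mother, child)
  expect_length(phases, 1L)
  expect_identical(phases, "ACG|ATG & ACG|CCT")

  geno <- geno_from_pairs(list(DAD = t(father), MOM = t(mother),
                               KID = t(child)), map)
  ped <- pedigree(data.frame(family_id = "F1",
                             subject_id = c("DAD", "MOM", "KID"),
                             father_id = c(NA, NA, "DAD"),
                             mother_id = c(NA, NA, "MOM")))
  res <- phase_family(ped, geno, map)
  hapstr <- apply(res$founders$alleles, 1, paste, collapse = "")
  expect_setequal(unname(hapstr[1:2]), c("ACG", "ATG"))   # father
  expect_setequal(unname(hapstr[3:4]), c("ACG", "CCT"))   # mother
  expect_identical(nrow(res$ambiguities), 0L)
  expect_true(isTRUE(check_phase_soundness(res, geno)))
})

test_that("a lone fully homozygous subject yields exactly one haplotype", {
  map <- tiny_map(positions = c(100, 200, 300))
  geno <- geno_from_pairs(list(S1 = rbind(c("A", "C", "G"),
                                          c("A", "C", "G"))), map)
  ped <- pedigree(data.frame(family_id = "F1", subject_id = "S1",
                             father_id = NA, mother_id = NA))
  res <- phase_family(ped, geno, map)
  expect_identical(n_haplotypes(res$founders), 1L)
  expect_identical(res$founders$info$source, "homozygous_sample")
  expect_identical(unname(res$founders$alleles[1, ]), c("A", "C", "G"))
})

test_that("markers heterozygous in every family member land in the ambiguity set", {
  map <- tiny_map(positions = c(100, 200, 300))
  father <- t(rbind(c("A", "G"), c("C", "C"), c("G", "G")))
  mother <- t(rbind(c("A", "G"), c("C", "C"), c("G", "T")))
  child <- t(rbind(c("A", "G"), c("C", "C"), c("G", "G")))
  geno <- geno_from_pairs(list(DAD = father, MOM = mother, KID = child), map)
  ped <- pedigree(data.frame(family_id = "F1",
                             subject_id = c("DAD", "MOM", "KID"),
                             father_id = c(NA, NA, "DAD"),
                             mother_id = c(NA, NA, "MOM")))
  res <- phase_family(ped, geno, map)
  # marker 1 is uninformative for both parents: both pairs ambiguous there
  expect_setequal(res$ambiguities$subject_id[res$ambiguities$marker_idx == 1],
                  c("DAD", "MOM"))
  expect_true(all(is.na(res$founders$alleles[, 1])))
})

test_that("a constructed paternal gamete switch is localized to its interval", {
  # 8 markers; father het A/G everywhere, mother homozygous A -> every
  # marker is paternally informative. Three children, child 1 switching
  # sources between markers 4 and 5.
  map <- tiny_map(positions = seq(100, by = 100, length.out = 8))
  fA <- rep("A", 8); fB <- rep("G", 8)
  mo <- rep("A", 8)
  pat1 <- c(fA[1:4], fB[5:8])          # recombinant
  pat2 <- fA; pat3 <- fB               # non-recombinant siblings
  mk <- function(pat) rbind(pat, mo)
  geno <- geno_from_pairs(list(
    DAD = rbind(fA, fB), MOM = rbind(mo, mo),
    C1 = mk(pat1), C2 = mk(pat2), C3 = mk(pat3)), map)
  ped <- pedigree(data.frame(
    family_id = "F1", subject_id = c("DAD", "MOM", "C1", "C2", "C3"),
    father_id = c(NA, NA, "DAD", "DAD", "DAD"),
    mother_id = c(NA, NA, "MOM", "MOM", "MOM")))
  res <- phase_family(ped, geno, map)
  xo <- detect_family_crossovers(res, map)
  expect_identical(nrow(xo), 1L)
  expect_identical(xo$child_id, "C1")
  expect_identical(xo$parent_role, "father")
  expect_identical(c(xo$from_idx, xo$to_idx), c(4L, 5L))
  expect_identical(c(xo$from_pos, xo$to_pos), c(400L, 500L))
  expect_false(xo$review)
})

test_that("no switches yields an empty crossover record", {
  map <- tiny_map(positions = c(100, 200, 300))
  geno <- geno_from_pairs(list(
    DAD = rbind(c("A", "C", "G"), c("G", "T", "T")),
    MOM = rbind(c("A", "C", "G"), c("A", "C", "G")),
    KID = rbind(c("A", "C", "G"), c("A", "C", "G"))), map)
  ped <- pedigree(data.frame(family_id = "F1",
                             subject_id = c("DAD", "MOM", "KID"),
                             father_id = c(NA, NA, "DAD"),
                             mother_id = c(NA, NA, "MOM")))
  res <- phase_family(ped, geno, map)
  expect_identical(nrow(detect_family_crossovers(res, map)), 0L)
})

test_that("Mendelian impossibilities flag and excise the marker, not the family", {
  map <- tiny_map(positions = c(100, 200, 300))
  geno <- geno_from_pairs(list(
    DAD = rbind(c("A", "C", "G"), c("A", "C", "G")),
    MOM = rbind(c("A", "C", "G"), c("A", "C", "G")),
    KID = rbind(c("A", "T", "G"), c("A", "T", "G"))), map)  # T unexplained
  ped <- pedigree(data.frame(family_id = "F1",
                             subject_id = c("DAD", "MOM", "KID"),
                             father_id = c(NA, NA, "DAD"),
                             mother_id = c(NA, NA, "MOM")))
  res <- phase_family(ped, geno, map)
  expect_identical(res$diagnostics$mendelian$marker_idx, 2L)
  expect_true(res$diagnostics$mendelian$null_suspect)  # homozygous child
  expect_true(all(is.na(res$founders$alleles[, 2])))
  expect_identical(unname(res$founders$alleles[1, 1]), "A")
})

test_that("ambiguity resolves toward the dominant context at flanking markers", {
  map <- tiny_map(positions = seq(100, by = 100, length.out = 5))
  # lone heterozygous subject: C/C T/T A/G C/C G/G with het at marker 3
  geno <- geno_from_pairs(list(S1 = rbind(c("C", "T", "A", "C", "G"),
                                          c("C", "T", "G", "C", "G"))), map)
  ped <- pedigree(data.frame(family_id = "F1", subject_id = "S1",
                             father_id = NA, mother_id = NA))
  res <- phase_family(ped, geno, map)
  expect_identical(res$ambiguities$marker_idx, 3L)
  # group context: dominant sequence carries A at the ambiguous marker
  dom_haps <- haps_from_strings(c(d1 = "CTACG", d2 = "CTACG"), map,
                                group_id = "G")
  dom <- compute_dominant_sequence(dom_haps, map)
  out <- assign_ambiguous_phase(res, map, dominant = dom)
  expect_identical(out$inferred$method, "dominant_context")
  # both haplotypes match the dominant at flanks; hap1 gets the dominant allele
  expect_identical(unname(out$founders$alleles["S1.1", 3]), "A")
  expect_identical(unname(out$founders$alleles["S1.2", 3]), "G")
  expect_true(isTRUE(check_phase_soundness(out, geno)))
})

test_that("dominant context discriminates between differing founder haplotypes", {
  map <- tiny_map(positions = seq(100, by = 100, length.out = 5))
  # father truly carries CTACG / GG.GT; marker 3 is heterozygous A/G in
  # every family member, hence ambiguous by segregation
  geno <- geno_from_pairs(list(
    DAD = rbind(c("C", "T", "A", "C", "G"), c("G", "G", "G", "G", "T")),
    MOM = rbind(c("C", "C", "A", "T", "G"), c("C", "C", "G", "T", "G")),
    C1  = rbind(c("C", "T", "A", "C", "G"), c("C", "C", "G", "T", "G")),
    C2  = rbind(c("G", "G", "G", "G", "T"), c("C", "C", "A", "T", "G"))), map)
  ped <- pedigree(data.frame(
    family_id = "F1", subject_id = c("DAD", "MOM", "C1", "C2"),
    father_id = c(NA, NA, "DAD", "DAD"),
    mother_id = c(NA, NA, "MOM", "MOM")))
  res <- phase_family(ped, geno, map)
  expect_true(all(c("DAD", "MOM") %in% res$ambiguities$subject_id))
  expect_true(all(res$ambiguities$marker_idx == 3L))
  dom <- compute_dominant_sequence(
    haps_from_strings(c(d1 = "CTACG", d2 = "CTACG"), map, group_id = "G"), map)
  out <- assign_ambiguous_phase(res, map, dominant = dom)
  # DAD.1 matches the dominant at the flanking markers 2 and 4 -> gets A
  expect_identical(unname(out$founders$alleles["DAD.1", ]),
                   c("C", "T", "A", "C", "G"))
  expect_identical(unname(out$founders$alleles["DAD.2", 3]), "G")
  expect_true(isTRUE(check_phase_soundness(out, geno)))
})

test_that("without context the lexical fallback is deterministic and flagged", {
  map <- tiny_map(positions = c(100, 200))
  geno <- geno_from_pairs(list(S1 = rbind(c("C", "G"), c("C", "A"))), map)
  ped <- pedigree(data.frame(family_id = "F1", subject_id = "S1",
                             father_id = NA, mother_id = NA))
  res <- assign_ambiguous_phase(phase_family(ped, geno, map), map)
  expect_identical(res$inferred$method, "lexical")
  expect_identical(unname(res$founders$alleles["S1.1", 2]), "A")
  expect_identical(unname(res$founders$alleles["S1.2", 2]), "G")
})

test_that("phasing is sound and founders exact on crossover-free synthetic families", {
  cfg <- sim_config(n_markers = 120, groups = c(G1 = 10L, G2 = 10L),
                    n_subregions = 4, p_r = 0.1, mu = 0, missing_rate = 0,
                    n_background_emit = 20, background_pool = 30,
                    pedigree_plan = list(n_families = 8,
                                         children_per_family = 3,
                                         intrafam_xo_prob = 0),
                    seed = 91)
  sim <- simulate_cohort(cfg)
  pc <- phase_cohort(sim$pedigree, sim$genotypes, sim$map,
                     resolve_ambiguity = FALSE)
  for (r in pc$results) {
    expect_true(isTRUE(check_phase_soundness(r, sim$genotypes)))
  }
  expect_identical(nrow(pc$crossovers), 0L)
  # every phased founder haplotype equals a planted truth haplotype at
  # all markers where segregation determined the phase (ambiguous
  # markers stay missing when unresolved, so equality there is exact)
  truth <- sim$truth_haps$alleles
  rec <- pc$haplotypes$alleles
  for (r in seq_len(nrow(rec))) {
    known <- !is.na(rec[r, ])
    expect_gt(mean(known), 0.8)
    hits <- apply(truth, 1, function(t) all(t[known] == rec[r, known]))
    expect_true(any(hits))
  }
})

test_that("planted intra-family crossovers between distinct parental haplotypes are recovered", {
  # force distinct founder haplotypes by drawing them all from the
  # background pool (no shared CEH ancestry)
  cfg <- sim_config(n_markers = 120, groups = c(G1 = 1L), n_subregions = 4,
                    p_r = 0, mu = 0, missing_rate = 0,
                    n_background_emit = 40, background_pool = 40,
                    pedigree_plan = list(n_families = 6,
                                         children_per_family = 3,
                                         intrafam_xo_prob = 1),
                    seed = 17)
  sim <- simulate_cohort(cfg)
  pc <- phase_cohort(sim$pedigree, sim$genotypes, sim$map,
                     resolve_ambiguity = TRUE)
  tr <- sim$truth$pedigree
  tr <- tr[!is.na(tr$xo_role), ]
  expect_gt(nrow(tr), 0L)
  det <- pc$crossovers
  matched <- vapply(seq_len(nrow(tr)), function(r) {
    any(det$child_id == tr$child_id[r] &
          det$parent_role == tr$xo_role[r] &
          det$from_idx < tr$xo_breakpoint_idx[r] &
          det$to_idx >= tr$xo_breakpoint_idx[r])
  }, logical(1))
  # a switch can only be bracketed between informative markers; when no
  # sibling pins the phase inside a sparse window the bracket may sit
  # beside the planted point, so recovery is near- but not always exact
  expect_gte(mean(matched), 0.85)
  # and every family yields at least one record
  expect_setequal(unique(det$family_id), unique(tr$family_id))
})
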