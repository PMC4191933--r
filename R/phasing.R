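#' Phase one family's genotypes by segregation analysis
#'
#' Reconstructs founder haplotypes from unphased genotypes in a nuclear
#' pedigree (two founder parents plus children) or from a lone subject.
#' At every marker where transmission is logically determined — a parent
#' homozygous, or a child allele uniquely attributable to one parent —
#' phase is fixed. Phase is linked across heterozygous markers by
#' minimizing source switches in the children's gametes (a switch that
#' survives minimization is an intra-family crossover; see
#' [detect_family_crossovers()]). Markers that stay logically
#' undetermined are surfaced in the ambiguity set, never guessed here;
#' [assign_ambiguous_phase()] resolves them afterwards against a group
#' dominant sequence or a documented deterministic fallback.
#'
#' A lone subject homozygous at every non-missing marker contributes a
#' single haplotype (`source = "homozygous_sample"`); any other founder
#' contributes two (`source = "pedigree_founder"`).
#'
#' Mendelian impossibilities do not abort the family: the marker is
#' flagged, excised (set missing) from the family's haplotypes, and
#' marked as a possible silent (null) allele when a homozygous child
#' faces a parent apparently lacking the allele.
#'
#' @param ped A [pedigree()] restricted to one family.
#' @param geno A [genotype_table()] covering the family's subjects.
#' @param map The [marker_map()].
#' @return A `phase_result` list: `family_id`; `founders` (a
#'   [haplotype_set()]); `founder_pairs` (data frame `subject_id`,
#'   `hap1_id`, `hap2_id`); `subject_haplotypes` (per subject a 2 x
#'   n-marker allele matrix, children's rows being their paternal and
#'   maternal gametes); `gamete_sources` (per child, per parent, the
#'   inferred source haplotype 1/2 along the map); `ambiguities` (data
#'   frame `subject_id`, `marker_idx`, `allele1`, `allele2`);
#'   `diagnostics` (`mendelian` data frame with `marker_idx` and
#'   `null_suspect`; `linkage_ties`, marker indices where phase linkage
#'   was ambiguous).
#' @export
phase_family <- function(ped, geno, map) {
  stopifnot(inherits(ped, "pedigree"), inherits(geno, "genotype_table"),
            inherits(map, "marker_map"))
  fam <- unique(ped$family_id)
  if (length(fam) != 1L) stop("phase_family expects exactly one family")
  idx <- match(ped$subject_id, geno$subject_id)
  if (anyNA(idx)) stop("genotypes missing for subject(s): ",
                       paste(ped$subject_id[is.na(idx)], collapse = ", "))
  n_mark <- nrow(map)
  has_geno <- vapply(idx, function(i)
    any(!is.na(geno$a1[i, ])) || any(!is.na(geno$a2[i, ])), logical(1))
  if (!any(has_geno)) stop("family ", fam, " has no genotyped subject")

  children <- ped$subject_id[!is.na(ped$father_id) | !is.na(ped$mother_id)]
  parents <- unique(stats::na.omit(c(ped$father_id, ped$mother_id)))

  if (length(children) > 0L) {
    fathers <- unique(stats::na.omit(ped$father_id[ped$subject_id %in% children]))
    mothers <- unique(stats::na.omit(ped$mother_id[ped$subject_id %in% children]))
    if (length(fathers) != 1L || length(mothers) != 1L ||
        length(setdiff(ped$subject_id, c(children, fathers, mothers))) > 0L) {
      stop("family ", fam, ": only nuclear families ",
           "(two founder parents plus children) or singletons are supported")
    }
    phase_nuclear(fam, fathers, mothers, children, geno, map)
  } else {
    phase_singletons(fam, ped$subject_id, geno, map)
  }
}

# genotype pair of one subject at one marker, as length-2 vector
geno_pair <- function(geno, subject, j) {
  i <- match(subject, geno$subject_id)
  c(geno$a1[i, j], geno$a2[i, j])
}

# Enumerate (paternal, maternal) splits of a child genotype. A parent with
# any missing call is unconstrained at that marker. Returns a 2-column
# matrix of valid splits (possibly 0 rows = Mendelian impossibility).
child_splits <- function(child_pair, father_pair, mother_pair) {
  if (anyNA(child_pair)) return(NULL)     # uninformative, not a violation
  f_known <- !anyNA(father_pair)
  m_known <- !anyNA(mother_pair)
  orders <- list(child_pair, rev(child_pair))
  ok <- vapply(orders, function(o) {
    (!f_known || o[1L] %in% father_pair) && (!m_known || o[2L] %in% mother_pair)
  }, logical(1))
  if (!any(ok)) return(matrix(character(0), nrow = 0L, ncol = 2L))
  splits <- do.call(rbind, orders[ok])
  # identical orders (homozygous child) collapse to one
  unique(splits)
}

phase_nuclear <- function(fam, father, mother, children, geno, map) {
  n_mark <- nrow(map)
  k <- length(children)

  # per-marker transmission determination
  pat <- matrix(NA_character_, nrow = k, ncol = n_mark,
                dimnames = list(children, NULL))  # paternal allele per child
  mat <- matrix(NA_character_, nrow = k, ncol = n_mark,
                dimnames = list(children, NULL))
  mendel <- integer(0)
  null_suspect <- logical(0)
  excised <- rep(FALSE, n_mark)

  for (j in seq_len(n_mark)) {
    fp <- geno_pair(geno, father, j)
    mp <- geno_pair(geno, mother, j)
    violated <- FALSE
    nullish <- FALSE
    for (ci in seq_len(k)) {
      cp <- geno_pair(geno, children[ci], j)
      sp <- child_splits(cp, fp, mp)
      if (is.null(sp)) next
      if (nrow(sp) == 0L) {
        violated <- TRUE
        # homozygous child vs a parent apparently lacking the allele:
        # consistent with a silent (null) allele in that parent
        if (cp[1L] == cp[2L]) nullish <- TRUE
        next
      }
      if (length(unique(sp[, 1L])) == 1L) pat[ci, j] <- sp[1L, 1L]
      if (length(unique(sp[, 2L])) == 1L) mat[ci, j] <- sp[1L, 2L]
    }
    if (violated) {
      mendel <- c(mendel, j)
      null_suspect <- c(null_suspect, nullish)
      excised[j] <- TRUE
      pat[, j] <- NA_character_
      mat[, j] <- NA_character_
    }
  }

  fa <- phase_parent(father, geno, map, pat, excised)
  mo <- phase_parent(mother, geno, map, mat, excised)

  # children's gametes and source vectors
  subject_haplotypes <- list()
  gamete_sources <- list()
  subject_haplotypes[[father]] <- fa$haps
  subject_haplotypes[[mother]] <- mo$haps
  for (ci in seq_len(k)) {
    ch <- children[ci]
    subject_haplotypes[[ch]] <- rbind(paternal = pat[ci, ],
                                      maternal = mat[ci, ])
    gamete_sources[[ch]] <- list(father = fa$sources[ci, ],
                                 mother = mo$sources[ci, ])
  }

  founder_alleles <- rbind(fa$haps, mo$haps)
  hap_ids <- c(paste0(father, c(".1", ".2")), paste0(mother, c(".1", ".2")))
  rownames(founder_alleles) <- hap_ids
  founders <- haplotype_set(founder_alleles, map, haplotype_id = hap_ids,
                            source = "pedigree_founder")
  amb <- rbind(fa$ambiguities, mo$ambiguities)
  structure(list(
    family_id = fam,
    founders = founders,
    founder_pairs = data.frame(
      subject_id = c(father, mother),
      hap1_id = c(hap_ids[1L], hap_ids[3L]),
      hap2_id = c(hap_ids[2L], hap_ids[4L]),
      stringsAsFactors = FALSE),
    subject_haplotypes = subject_haplotypes,
    gamete_sources = gamete_sources,
    ambiguities = amb,
    diagnostics = list(
      mendelian = data.frame(marker_idx = mendel,
                             null_suspect = null_suspect),
      linkage_ties = sort(unique(c(fa$ties, mo$ties))))),
    class = "phase_result")
}

# Phase one parent's haplotype pair from child transmissions.
# `trans` is children x markers: the allele this parent transmitted to
# each child, where determined. The per-marker allele labeling (which
# allele belongs to haplotype 1) is chosen by exact minimization of the
# total number of gamete source switches across all children — a small
# Viterbi over the children's source-state vectors, so a crossover in
# one meiosis is never absorbed into relabeling when other meioses pin
# the phase. Ties are broken deterministically toward the allele-sorted
# labeling and flagged as linkage ambiguity.
phase_parent <- function(parent, geno, map, trans, excised) {
  n_mark <- nrow(map)
  k <- nrow(trans)
  haps <- matrix(NA_character_, nrow = 2L, ncol = n_mark)
  sources <- matrix(NA_integer_, nrow = k, ncol = n_mark)
  amb <- data.frame(subject_id = character(0), marker_idx = integer(0),
                    allele1 = character(0), allele2 = character(0),
                    stringsAsFactors = FALSE)

  het_pairs <- vector("list", n_mark)
  obs <- vector("list", n_mark)       # child's allele index in sorted pair
  link_markers <- integer(0)
  for (j in seq_len(n_mark)) {
    if (excised[j]) next
    gp <- geno_pair(geno, parent, j)
    if (anyNA(gp)) next               # parent unsequenced: leave missing
    if (gp[1L] == gp[2L]) {
      haps[, j] <- gp[1L]
      next
    }
    pair <- sort(gp)
    o <- match(trans[, j], pair)
    if (all(is.na(o))) {
      amb <- rbind(amb, data.frame(subject_id = parent, marker_idx = j,
                                   allele1 = pair[1L], allele2 = pair[2L],
                                   stringsAsFactors = FALSE))
      next
    }
    het_pairs[[j]] <- pair
    obs[[j]] <- o
    link_markers <- c(link_markers, j)
  }

  # Viterbi over (source per child) states; two labeling choices per marker
  states <- list(list(s = rep(NA_integer_, k), cost = 0L, path = integer(0)))
  first_link <- TRUE
  for (j in link_markers) {
    o <- obs[[j]]
    nxt <- list()
    # the overall phase is defined only up to a swap of the two
    # haplotypes; pin the first linked marker to the sorted labeling
    x_choices <- if (first_link) 0L else c(0L, 1L)
    first_link <- FALSE
    for (st in states) {
      for (x in x_choices) {
        s_new <- st$s
        s_obs <- if (x == 0L) o else 3L - o
        informed <- !is.na(s_obs)
        switches <- sum(!is.na(st$s[informed]) &
                          st$s[informed] != s_obs[informed])
        s_new[informed] <- s_obs[informed]
        key <- paste(c(x_last = NA, s_new), collapse = ",")
        cand <- list(s = s_new, cost = st$cost + switches,
                     path = c(st$path, x))
        old <- nxt[[key]]
        if (is.null(old) || cand$cost < old$cost ||
            (cand$cost == old$cost &&
               paste(cand$path, collapse = "") < paste(old$path, collapse = ""))) {
          nxt[[key]] <- cand
        }
      }
    }
    states <- nxt
  }
  ties <- integer(0)
  if (length(link_markers) > 0L) {
    costs <- vapply(states, `[[`, integer(1), "cost")
    best_cost <- min(costs)
    bests <- states[costs == best_cost]
    paths <- vapply(bests, function(b) paste(b$path, collapse = ""), character(1))
    best <- bests[[order(paths)[1L]]]
    if (length(bests) > 1L) {
      # phase linkage not unique: flag markers where optimal paths differ
      pm <- do.call(rbind, lapply(bests, `[[`, "path"))
      ties <- link_markers[apply(pm, 2L, function(col) length(unique(col)) > 1L)]
    }
    for (q in seq_along(link_markers)) {
      j <- link_markers[q]
      x <- best$path[q]
      pair <- het_pairs[[j]]
      haps[1L, j] <- if (x == 0L) pair[1L] else pair[2L]
      haps[2L, j] <- if (x == 0L) pair[2L] else pair[1L]
      o <- obs[[j]]
      sources[, j] <- if (x == 0L) o else 3L - o
    }
  }
  list(haps = haps, sources = sources, ambiguities = amb, ties = ties)
}

phase_singletons <- function(fam, subjects, geno, map) {
  n_mark <- nrow(map)
  founder_rows <- list()
  sources <- character(0)
  founder_pairs <- data.frame(subject_id = character(0), hap1_id = character(0),
                              hap2_id = character(0), stringsAsFactors = FALSE)
  subject_haplotypes <- list()
  amb <- data.frame(subject_id = character(0), marker_idx = integer(0),
                    allele1 = character(0), allele2 = character(0),
                    stringsAsFactors = FALSE)
  for (s in subjects) {
    i <- match(s, geno$subject_id)
    g1 <- geno$a1[i, ]; g2 <- geno$a2[i, ]
    het <- which(!is.na(g1) & !is.na(g2) & g1 != g2)
    if (length(het) == 0L) {
      hap <- ifelse(is.na(g1), g2, g1)  # homozygous throughout
      founder_rows[[paste0(s, ".1")]] <- hap
      sources <- c(sources, "homozygous_sample")
      founder_pairs <- rbind(founder_pairs, data.frame(
        subject_id = s, hap1_id = paste0(s, ".1"), hap2_id = NA_character_,
        stringsAsFactors = FALSE))
      subject_haplotypes[[s]] <- rbind(hap, hap)
    } else {
      h1 <- h2 <- ifelse(!is.na(g1) & !is.na(g2) & g1 == g2, g1, NA_character_)
      for (j in het) {
        pair <- sort(c(g1[j], g2[j]))
        amb <- rbind(amb, data.frame(subject_id = s, marker_idx = j,
                                     allele1 = pair[1L], allele2 = pair[2L],
                                     stringsAsFactors = FALSE))
      }
      founder_rows[[paste0(s, ".1")]] <- h1
      founder_rows[[paste0(s, ".2")]] <- h2
      sources <- c(sources, "pedigree_founder", "pedigree_founder")
      founder_pairs <- rbind(founder_pairs, data.frame(
        subject_id = s, hap1_id = paste0(s, ".1"), hap2_id = paste0(s, ".2"),
        stringsAsFactors = FALSE))
      subject_haplotypes[[s]] <- rbind(h1, h2)
    }
  }
  alleles <- do.call(rbind, founder_rows)
  founders <- haplotype_set(alleles, map, haplotype_id = names(founder_rows),
                            source = sources)
  structure(list(
    family_id = fam, founders = founders, founder_pairs = founder_pairs,
    subject_haplotypes = subject_haplotypes,
    gamete_sources = list(), ambiguities = amb,
    diagnostics = list(
      mendelian = data.frame(marker_idx = integer(0),
                             null_suspect = logical(0)),
      linkage_ties = integer(0))),
    class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf(
    "phase_result [family %s]: %d founder haplotype(s), %d ambiguous marker assignment(s), %d Mendelian flag(s)\n",
    x$family_id, n_haplotypes(x$founders), nrow(x$ambiguities),
    nrow(x$diagnostics$mendelian)))
  invisible(x)
}

#' Detect intra-family crossovers from phased gametes
#'
#' A child whose inferred paternal (or maternal) gamete switches source
#' haplotype along the map yields one crossover record per switch, with
#' the bounding interval (last informative marker of one source, first
#' informative marker of the other). Gametes with more than one switch
#' produce one record each and flag the family for review. Recombinant
#' gametes are never part of the founder haplotype list.
#'
#' @param phase A [phase_family()] result.
#' @param map The [marker_map()].
#' @return Data frame `family_id`, `child_id`, `parent_role`
#'   (`"father"`/`"mother"`), `from_idx`, `to_idx` (map indices bounding
#'   the switch), `from_pos`, `to_pos`, `review` (TRUE when that gamete
#'   carries >1 switch).
#' @export
detect_family_crossovers <- function(phase, map) {
  stopifnot(inherits(phase, "phase_result"), inherits(map, "marker_map"))
  rows <- list()
  for (child in names(phase$gamete_sources)) {
    for (role in c("father", "mother")) {
      src <- phase$gamete_sources[[child]][[role]]
      inf <- which(!is.na(src))
      if (length(inf) < 2L) next
      switches <- inf[which(diff(src[inf]) != 0L) + 1L]
      prevs <- inf[which(diff(src[inf]) != 0L)]
      if (length(switches) == 0L) next
      for (q in seq_along(switches)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = phase$family_id, child_id = child, parent_role = role,
          from_idx = prevs[q], to_idx = switches[q],
          from_pos = map$position_bp[prevs[q]],
          to_pos = map$position_bp[switches[q]],
          review = length(switches) > 1L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(family_id = character(0), child_id = character(0),
               parent_role = character(0), from_idx = integer(0),
               to_idx = integer(0), from_pos = integer(0),
               to_pos = integer(0), review = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Resolve residual phase ambiguity
#'
#' For every marker left ambiguous by segregation (all informative
#' subjects heterozygous, or a lone heterozygous subject), one allele is
#' assigned to one of the two haplotypes so as to be consistent with the
#' surrounding unambiguous markers: the haplotype matching the group
#' dominant sequence at the nearest non-missing unambiguous marker on
#' each side receives the dominant allele. When no dominant context is
#' available (or neither haplotype matches it at the flanks), a fallback
#' assigns the lexically lower allele to the lower-numbered haplotype of
#' the pair. Every resolved call is flagged as inferred.
#'
#' @param phase A [phase_family()] result.
#' @param map The [marker_map()].
#' @param dominant Optional [compute_dominant_sequence()] result giving
#'   group context, or a named list of them keyed by `group_id` with a
#'   `groups` vector naming each founder subject's group.
#' @param groups Optional named character vector: founder `subject_id` ->
#'   `group_id`, used when `dominant` is a list.
#' @return The `phase_result` with ambiguous alleles filled into
#'   `founders` and `subject_haplotypes`, and an added data frame
#'   `inferred` (`subject_id`, `marker_idx`, `hap1_allele`,
#'   `hap2_allele`, `method` = `"dominant_context"` or `"lexical"`).
#' @export
assign_ambiguous_phase <- function(phase, map, dominant = NULL, groups = NULL) {
  stopifnot(inherits(phase, "phase_result"), inherits(map, "marker_map"))
  amb <- phase$ambiguities
  inferred <- data.frame(subject_id = character(0), marker_idx = integer(0),
                         hap1_allele = character(0), hap2_allele = character(0),
                         method = character(0), stringsAsFactors = FALSE)
  if (nrow(amb) == 0L) {
    phase$inferred <- inferred
    return(phase)
  }
  for (r in seq_len(nrow(amb))) {
    s <- amb$subject_id[r]; j <- amb$marker_idx[r]
    alleles <- c(amb$allele1[r], amb$allele2[r])   # lexically sorted on entry
    pair_ids <- phase$founder_pairs[phase$founder_pairs$subject_id == s, ]
    h <- phase$subject_haplotypes[[s]]
    dom <- dominant
    if (is.list(dominant) && !inherits(dominant, "dominant_sequence")) {
      gid <- if (!is.null(groups)) unname(groups[s]) else NA_character_
      dom <- if (!is.na(gid) && gid %in% names(dominant)) dominant[[gid]] else NULL
    }
    assigned <- FALSE
    if (!is.null(dom)) {
      pick <- dominant_context_pick(h, dom, j, alleles)
      if (!is.na(pick$hap)) {
        a_dom <- pick$dom_allele
        a_oth <- setdiff(alleles, a_dom)
        if (length(a_oth) == 0L) a_oth <- a_dom
        if (pick$hap == 1L) {
          h[1L, j] <- a_dom; h[2L, j] <- a_oth[1L]
        } else {
          h[1L, j] <- a_oth[1L]; h[2L, j] <- a_dom
        }
        inferred <- rbind(inferred, data.frame(
          subject_id = s, marker_idx = j, hap1_allele = h[1L, j],
          hap2_allele = h[2L, j], method = "dominant_context",
          stringsAsFactors = FALSE))
        assigned <- TRUE
      }
    }
    if (!assigned) {
      h[1L, j] <- alleles[1L]; h[2L, j] <- alleles[2L]
      inferred <- rbind(inferred, data.frame(
        subject_id = s, marker_idx = j, hap1_allele = alleles[1L],
        hap2_allele = alleles[2L], method = "lexical",
        stringsAsFactors = FALSE))
    }
    phase$subject_haplotypes[[s]] <- h
    # propagate into the founder haplotype set
    ids <- c(pair_ids$hap1_id[1L], pair_ids$hap2_id[1L])
    for (w in 1:2) {
      if (!is.na(ids[w])) {
        ridx <- match(ids[w], phase$founders$info$haplotype_id)
        phase$founders$alleles[ridx, j] <- h[w, j]
      }
    }
  }
  phase$inferred <- inferred
  phase
}

# Which of the subject's two haplotypes matches the dominant sequence at
# the nearest unambiguous non-missing flanking markers of j? Returns the
# haplotype index and the dominant allele at j when discrimination and a
# usable dominant allele exist.
dominant_context_pick <- function(h, dom, j, alleles) {
  loc <- match(j, dom$marker_idx)
  if (is.na(loc) || dom$status[loc] != "defined" ||
      !(dom$dominant[loc] %in% alleles)) {
    return(list(hap = NA_integer_, dom_allele = NA_character_))
  }
  usable <- which(dom$status == "defined" &
                    !is.na(h[1L, dom$marker_idx]) &
                    !is.na(h[2L, dom$marker_idx]))
  left <- usable[usable < loc]
  right <- usable[usable > loc]
  flanks <- c(if (length(left) > 0L) max(left),
              if (length(right) > 0L) min(right))
  if (length(flanks) == 0L) {
    return(list(hap = NA_integer_, dom_allele = NA_character_))
  }
  m1 <- all(h[1L, dom$marker_idx[flanks]] == dom$dominant[flanks])
  m2 <- all(h[2L, dom$marker_idx[flanks]] == dom$dominant[flanks])
  if (!m1 && !m2) return(list(hap = NA_integer_, dom_allele = NA_character_))
  # both flanks matching (haplotypes identical there): the dominant allele
  # goes deterministically to the first haplotype of the pair
  list(hap = if (m1) 1L else 2L, dom_allele = dom$dominant[loc])
}

#' Phase every family of a cohort
#'
#' Convenience driver: runs [phase_family()] per family, optionally
#' resolves residual ambiguity, and pools the founder haplotypes.
#'
#' @param ped A [pedigree()] (any number of families).
#' @param geno A [genotype_table()].
#' @param map The [marker_map()].
#' @param resolve_ambiguity Apply [assign_ambiguous_phase()] with the
#'   lexical fallback (no group context) per family.
#' @return List: `haplotypes` (pooled founder [haplotype_set()]),
#'   `results` (per-family `phase_result`s), `crossovers` (pooled
#'   [detect_family_crossovers()] records).
#' @export
phase_cohort <- function(ped, geno, map, resolve_ambiguity = FALSE) {
  fams <- unique(ped$family_id)
  results <- vector("list", length(fams))
  names(results) <- fams
  for (f in fams) {
    sub <- pedigree(ped[ped$family_id == f, , drop = FALSE])
    pr <- phase_family(sub, geno, map)
    if (resolve_ambiguity) pr <- assign_ambiguous_phase(pr, map)
    results[[f]] <- pr
  }
  alleles <- do.call(rbind, lapply(results, function(r) r$founders$alleles))
  sources <- unlist(lapply(results, function(r) r$founders$info$source),
                    use.names = FALSE)
  ids <- unlist(lapply(results, function(r) r$founders$info$haplotype_id),
                use.names = FALSE)
  pooled <- haplotype_set(alleles, map, haplotype_id = ids, source = sources)
  xo <- do.call(rbind, lapply(results, detect_family_crossovers, map = map))
  rownames(xo) <- NULL
  list(haplotypes = pooled, results = results, crossovers = xo)
}

#' Check phasing soundness against observed genotypes
#'
#' Re-derives each subject's genotype from its two assigned haplotypes
#' and compares with the observed table, treating missing as compatible
#' with anything on its own side of the pair.
#'
#' @param phase A [phase_family()] result.
#' @param geno The observed [genotype_table()].
#' @return `TRUE` when every non-missing observed pair is reproduced;
#'   otherwise a character vector describing the mismatches.
#' @export
check_phase_soundness <- function(phase, geno) {
  problems <- character(0)
  for (s in names(phase$subject_haplotypes)) {
    h <- phase$subject_haplotypes[[s]]
    i <- match(s, geno$subject_id)
    for (j in seq_len(ncol(h))) {
      obs <- unname(sort(c(geno$a1[i, j], geno$a2[i, j]), na.last = TRUE))
      der <- unname(sort(c(h[1L, j], h[2L, j]), na.last = TRUE))
      if (anyNA(obs) || anyNA(der)) next
      if (!identical(obs, der)) {
        problems <- c(problems, sprintf("%s marker %d: observed %s derived %s",
                                        s, j, paste(obs, collapse = "/"),
                                        paste(der, collapse = "/")))
      }
    }
  }
  if (length(problems) == 0L) TRUE else problems
}
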