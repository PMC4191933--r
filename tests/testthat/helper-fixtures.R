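# Small hand-built fixtures shared across test files.

# A map of n SNP markers at the given positions (default 6 markers,
# 10 kb apart), one amplicon per pair, all in one sub-region unless
# subregion_id is supplied.
tiny_map <- function(positions = seq(1e6, by = 1e4, length.out = 6),
                     subregion_id = 1L, kind = "SNP") {
  n <- length(positions)
  marker_map(data.frame(
    marker_id = sprintf("m%d", seq_len(n)),
    rs_id = sprintf("rs%d", seq_len(n)),
    position_bp = as.integer(positions),
    kind = rep_len(kind, n),
    amplicon_id = sprintf("amp%d", (seq_len(n) + 1L) %/% 2L),
    subregion_id = rep_len(subregion_id, n),
    stringsAsFactors = FALSE))
}

# haplotype_set from a character vector of allele strings like "ACGTAC"
haps_from_strings <- function(strings, map, ids = names(strings),
                              group_id = NA_character_) {
  m <- do.call(rbind, lapply(strings, function(s) strsplit(s, "")[[1]]))
  if (is.null(ids)) ids <- paste0("h", seq_along(strings))
  haplotype_set(m, map, haplotype_id = ids, source = "pedigree_founder",
                group_id = group_id)
}

# Independent brute-force phasing oracle for a trio: enumerates every
# assignment of parental genotypes into ordered haplotype pairs and every
# transmission choice, keeping those that reproduce the child's genotype.
# Returns the set of consistent {father pair, mother pair} phase
# configurations (unordered within each parent).
enumerate_trio_phases <- function(father_geno, mother_geno, child_geno) {
  n <- nrow(father_geno)
  split_pairs <- function(g) {
    # both orders of each marker's pair -> all 2^n hap-pair configurations
    opts <- lapply(seq_len(n), function(j) {
      u <- unique(list(g[j, ], rev(g[j, ])))
      u
    })
    grids <- expand.grid(lapply(opts, seq_along))
    lapply(seq_len(nrow(grids)), function(r) {
      h1 <- vapply(seq_len(n), function(j) opts[[j]][[grids[r, j]]][1], "")
      h2 <- vapply(seq_len(n), function(j) opts[[j]][[grids[r, j]]][2], "")
      list(h1 = h1, h2 = h2)
    })
  }
  canon <- function(pair) {
    key <- sort(c(paste(pair$h1, collapse = ""), paste(pair$h2, collapse = "")))
    paste(key, collapse = "|")
  }
  out <- character(0)
  for (fp in split_pairs(father_geno)) {
    for (mp in split_pairs(mother_geno)) {
      for (ft in 1:2) for (mt in 1:2) {
        pat <- if (ft == 1) fp$h1 else fp$h2
        mat <- if (mt == 1) mp$h1 else mp$h2
        ok <- all(vapply(seq_len(n), function(j) {
          setequal(sort(c(pat[j], mat[j])), sort(child_geno[j, ])) &&
            identical(sort(c(pat[j], mat[j])), sort(child_geno[j, ]))
        }, logical(1)))
        if (ok) out <- c(out, paste(canon(fp), canon(mp), sep = " & "))
      }
    }
  }
  unique(out)
}

# Build a genotype_table directly from per-subject allele pair matrices.
geno_from_pairs <- function(pairs, map) {
  a1 <- do.call(rbind, lapply(pairs, function(p) p[1, ]))
  a2 <- do.call(rbind, lapply(pairs, function(p) p[2, ]))
  rownames(a1) <- rownames(a2) <- names(pairs)
  genotype_table(a1, a2, map, subject_id = names(pairs))
}
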