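# Shared fixtures: the two-pathway killer network (activator-gated S35,
# suppressor-gated S24) and independent brute-force oracles.

pk_s35 <- function(s = survival_s(0.89), c = 0) {
  killer_system(
    killer = locus("S35", "chr1", 3060000, "killer"),
    partner = locus("INK", "chr5", 1300000, "partner"),
    partner_mode = "activator", targeted_allele = "J",
    survival_s = s, collateral_c = c
  )
}

pk_s24 <- function(s = 0.05, c = 0) {
  killer_system(
    killer = locus("S24", "chr5", 1000000, "killer"),
    partner = locus("EFS", "chr2", 26000000, "partner"),
    partner_mode = "suppressor", targeted_allele = "J",
    survival_s = s, collateral_c = c
  )
}

# S35 (chr1) and its activator INK (chr5): physically unlinked
pk_map2 <- function() {
  genetic_map(c("S35", "INK"), c("chr1", "chr5"), c(10, 25),
              pos_bp = c(3060000L, 1300000L))
}

# Pearson chi-square written out longhand, independent of gof_test internals
oracle_pearson <- function(obs, ratio) {
  expected <- sum(obs) * ratio / sum(ratio)
  x2 <- 0
  for (i in seq_along(obs)) x2 <- x2 + (obs[i] - expected[i])^2 / expected[i]
  x2
}

# Exact multinomial p by brute-force enumeration over expand.grid
oracle_exact_multinomial <- function(obs, probs) {
  n <- sum(obs)
  m <- length(obs)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:n), m - 1L)))
  last <- n - rowSums(grid)
  cnts <- cbind(grid, last)[last >= 0, , drop = FALSE]
  p <- apply(cnts, 1L, function(x) stats::dmultinom(x, prob = probs))
  p_obs <- stats::dmultinom(obs, prob = probs)
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# Brute-force admissibility over markers and gap midpoints, scanning each
# line positionally (independent of the matrix logic in infer_interval).
oracle_admissible <- function(panel, carrier_rule) {
  carrier_of <- function(g) {
    if (is.na(g)) return(NA)
    switch(carrier_rule,
           "dominant-donor" = g %in% c("H", "II"),
           "het" = g == "H",
           "recessive-donor" = g == "II")
  }
  pos <- panel$map$pos_bp
  L <- length(pos)
  # candidates in extended order: marker1, gap12, marker2, ...
  cand_kind <- rep(c("marker", "gap"), length.out = 2L * L - 1L)
  ok <- rep(TRUE, 2L * L - 1L)
  for (i in seq_len(nrow(panel$genotypes))) {
    geno <- panel$genotypes[i, ]
    obs <- panel$phenotype[i] == "carrier"
    states <- vapply(geno, carrier_of, logical(1))
    for (e in seq_along(ok)) {
      if (cand_kind[e] == "marker") {
        st <- states[(e + 1L) %/% 2L]
      } else {
        j <- e %/% 2L
        left <- states[seq_len(j)]
        right <- states[(j + 1L):L]
        gl <- if (any(!is.na(left))) left[max(which(!is.na(left)))] else NA
        gr <- if (any(!is.na(right))) right[min(which(!is.na(right)))] else NA
        st <- if (!is.na(gl) && !is.na(gr) && gl == gr) gl else NA
      }
      if (!is.na(st) && st != obs) ok[e] <- FALSE
    }
  }
  ok
}

# Rebuild a panel from a subset of its lines (for monotonicity checks)
subset_panel <- function(panel, lines) {
  recombinant_panel(panel$map, panel$genotypes[lines, , drop = FALSE],
                    panel$phenotype[lines], panel$line_id[lines])
}
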