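# Synthetic-data generators: progeny counts, selfed genotype tables with
# misgenotyping/missingness, and recombinant fine-mapping panels with a
# known planted causal position. All generators are deterministic under a
# fixed seed.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate testcross progeny counts
#'
#' Draws `n_H ~ Binomial(n, k)` heterozygous progeny (favoured allele
#' transmitted) out of `n` testcross progeny; the rest are `JJ`.
#'
#' @param k Male transmission parameter in `[0, 1]`.
#' @param n Number of progeny (> 0).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A [count_data()] with `n_H` and `n_JJ` filled.
#' @examples
#' gen_testcross_counts(0.89, 151, seed = 1)
#' @export
gen_testcross_counts <- function(k, n, seed = NULL) {
  .check_k(k)
  stopifnot(n > 0, n == round(n))
  .with_seed(seed, {
    n_H <- stats::rbinom(1L, as.integer(n), k)
    count_data(n_H = n_H, n_JJ = as.integer(n) - n_H)
  })
}

#' Simulate a selfed-progeny genotype table at one marker
#'
#' Draws genotypes from [selfing_freq()] for a killer-locus marker, then
#' applies optional misgenotyping (a genotype is replaced by one of the
#' other two codes) and missing-data injection.
#'
#' @inheritParams gen_testcross_counts
#' @param marker Marker column name, default `"S35"`.
#' @param misgenotyping_rate Probability a genotype is flipped to a random
#'   other code.
#' @param na_rate Probability a genotype is replaced by `NA`.
#' @return A [genotype_table()] with columns `sample_id` and `marker`.
#' @examples
#' tab <- gen_selfed_table(0.89, 500, seed = 1)
#' estimate_k(count_genotypes(tab, "S35"), "selfing")
#' @export
gen_selfed_table <- function(k, n, seed = NULL, marker = "S35",
                             misgenotyping_rate = 0, na_rate = 0) {
  .check_k(k)
  if (!is.numeric(n) || n <= 0 || n != round(n)) stop("n must be a positive integer")
  stopifnot(misgenotyping_rate >= 0, misgenotyping_rate <= 1,
            na_rate >= 0, na_rate <= 1)
  p <- selfing_freq(k)
  .with_seed(seed, {
    g <- sample(names(p), n, replace = TRUE, prob = p)
    flip <- stats::runif(n) < misgenotyping_rate
    if (any(flip))
      g[flip] <- vapply(g[flip],
                        function(x) sample(setdiff(GENOTYPE_CODES, x), 1L),
                        character(1))
    g[stats::runif(n) < na_rate] <- NA_character_
    df <- data.frame(sample_id = sprintf("SP%04d", seq_len(n)),
                     stringsAsFactors = FALSE)
    df[[marker]] <- g
    genotype_table(df)
  })
}

#' Count genotype classes at a marker of a genotype table
#'
#' @param table A [genotype_table()].
#' @param marker Marker column name.
#' @return A [count_data()] (NA genotypes are dropped).
#' @export
count_genotypes <- function(table, marker) {
  stopifnot(inherits(table, "genotype_table"))
  if (!marker %in% names(table)) stop("marker '", marker, "' is not in the table")
  g <- table[[marker]]
  g <- g[!is.na(g)]
  count_data(n_II = sum(g == "II"), n_H = sum(g == "H"), n_JJ = sum(g == "JJ"))
}

#' Generate a recombinant fine-mapping panel with a planted causal position
#'
#' Markers are spaced over `span_bp` on one chromosome. Each line carries a
#' single breakpoint placed uniformly within the marker span, with the donor
#' segment on a random side; donor-segment genotypes are `II` or `H`
#' depending on `carrier_rule` (`H` for the gametophytic `"het"` rule, `II`
#' or `H` at random for `"dominant-donor"`). The phenotype is assigned
#' deterministically from the genotype at `causal_pos` under `carrier_rule`,
#' so [infer_interval()] must return an interval containing `causal_pos`.
#'
#' @param n_markers Number of markers (>= 2).
#' @param n_lines Number of recombinant lines (>= 1).
#' @param causal_pos True causal position in bp; must fall within the marker
#'   span.
#' @param carrier_rule Carrier rule passed through to phenotype assignment
#'   (see [infer_interval()]).
#' @param seed Optional integer seed.
#' @param chrom Chromosome label.
#' @param span_bp Two-element range of marker positions in bp.
#' @return List with `panel` (a [recombinant_panel()]) and `truth`
#'   (`causal_pos`, per-line `breakpoint` and `donor_side`).
#' @examples
#' g <- gen_recombinant_panel(8, 20, causal_pos = 2500000, seed = 1)
#' infer_interval(g$panel)
#' @export
gen_recombinant_panel <- function(n_markers, n_lines, causal_pos,
                                  carrier_rule = "dominant-donor", seed = NULL,
                                  chrom = "chr1", span_bp = c(1e6, 4e6)) {
  stopifnot(n_markers >= 2, n_lines >= 1, length(span_bp) == 2L,
            span_bp[1] < span_bp[2])
  if (causal_pos < span_bp[1] || causal_pos > span_bp[2])
    stop("causal_pos must lie within span_bp")
  is_carrier_geno <- .carrier_predicate(carrier_rule)
  .with_seed(seed, {
    pos <- sort(round(seq(span_bp[1], span_bp[2], length.out = n_markers) +
                        stats::runif(n_markers, -0.25, 0.25) *
                        diff(span_bp) / n_markers))
    pos[1] <- round(span_bp[1])
    pos[n_markers] <- round(span_bp[2])
    pos <- as.integer(pos)
    while (anyDuplicated(pos)) pos <- as.integer(sort(pos + cumsum(duplicated(pos))))
    map <- data.frame(marker = sprintf("m%02d", seq_len(n_markers)),
                      chrom = chrom, pos_bp = pos, stringsAsFactors = FALSE)
    donor_code <- switch(carrier_rule,
      het = "H",
      `recessive-donor` = "II",
      `dominant-donor` = NA_character_ # chosen per line below
    )
    breakpoint <- stats::runif(n_lines, min(pos), max(pos))
    donor_side <- sample(c("left", "right"), n_lines, replace = TRUE)
    geno <- matrix(NA_character_, n_lines, n_markers,
                   dimnames = list(NULL, map$marker))
    phen <- character(n_lines)
    for (i in seq_len(n_lines)) {
      dc <- if (is.na(donor_code)) sample(c("II", "H"), 1L) else donor_code
      donor_at <- if (donor_side[i] == "left") pos <= breakpoint[i] else pos > breakpoint[i]
      geno[i, ] <- ifelse(donor_at, dc, "JJ")
      causal_donor <- if (donor_side[i] == "left")
        causal_pos <= breakpoint[i] else causal_pos > breakpoint[i]
      code_at_causal <- if (causal_donor) dc else "JJ"
      phen[i] <- if (is_carrier_geno(code_at_causal)) "carrier" else "noncarrier"
    }
    list(
      panel = recombinant_panel(map, geno, phen),
      truth = list(causal_pos = causal_pos, breakpoint = breakpoint,
                   donor_side = donor_side, carrier_rule = carrier_rule)
    )
  })
}
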