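# Forward Monte-Carlo simulation of multilocus populations under gamete
# killing: Haldane recombination, male-side rejection sampling of targeted
# gametes, cross designs (F2, testcross, backcross, SSD to RI lines), and a
# two-locus pseudo-linkage statistic.

#' Genetic map of loci used by the simulator
#'
#' Loci on distinct chromosomes segregate independently; within a chromosome
#' recombination between adjacent loci follows the Haldane map function on
#' centimorgan distances.
#'
#' @param marker Character vector of locus names (unique).
#' @param chrom Chromosome label per locus.
#' @param cM Map position in centimorgans (non-negative, non-decreasing
#'   within each chromosome).
#' @param pos_bp Optional physical positions (base pairs).
#' @return A data frame of class `genetic_map`.
#' @examples
#' genetic_map(c("S35", "INK"), c("chr1", "chr5"), c(10, 25))
#' @export
genetic_map <- function(marker, chrom, cM, pos_bp = NULL) {
  stopifnot(length(marker) == length(chrom), length(marker) == length(cM))
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (any(cM < 0)) stop("cM positions must be non-negative")
  m <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                  cM = as.numeric(cM), stringsAsFactors = FALSE)
  if (!is.null(pos_bp)) m$pos_bp <- as.integer(pos_bp)
  for (ch in unique(m$chrom)) {
    if (is.unsorted(m$cM[m$chrom == ch]))
      stop("cM positions must be non-decreasing within chromosome ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Cross design for the population simulator
#'
#' @param type One of `"F2"` (selfed F1), `"testcross"` (heterozygote x JJ
#'   tester), `"backcross"` (synonym of testcross with selectable recurrent
#'   allele), `"SSD_RI"` (single-seed descent to recombinant inbred lines).
#' @param n Number of offspring (or RI lines); > 0.
#' @param generations Selfing generations for `SSD_RI` (>= 1); ignored
#'   otherwise.
#' @param seed Optional integer seed; the simulation is bit-reproducible
#'   under a fixed seed.
#' @param het_parent For testcross/backcross: which parent is the
#'   heterozygote, `"male"` (killing can act) or `"female"` (Mendelian).
#' @param recurrent_allele Tester/recurrent parent allele, `"J"` (default)
#'   or `"I"`.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(type = c("F2", "testcross", "backcross", "SSD_RI"),
                         n, generations = 1L, seed = NULL,
                         het_parent = c("male", "female"),
                         recurrent_allele = c("J", "I")) {
  type <- match.arg(type)
  het_parent <- match.arg(het_parent)
  recurrent_allele <- match.arg(recurrent_allele)
  stopifnot(is.numeric(n), length(n) == 1L, n > 0, n == round(n))
  if (type == "SSD_RI" && generations < 1) stop("SSD_RI requires generations >= 1")
  if (generations < 0) stop("generations must be non-negative")
  structure(
    list(type = type, n = as.integer(n), generations = as.integer(generations),
         seed = seed, het_parent = het_parent, recurrent_allele = recurrent_allele),
    class = "cross_design"
  )
}

.haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

.geno_codes <- function(a, b) {
  ifelse(a == "I" & b == "I", "II", ifelse(a == "J" & b == "J", "JJ", "H"))
}

# One meiotic haplotype per row: independent 0.5 start per chromosome, one
# Bernoulli crossover draw per adjacent interval (Haldane probability).
.recombine <- function(hapA, hapB, map) {
  n <- nrow(hapA)
  useB <- matrix(0L, n, ncol(hapA))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    len <- length(idx)
    par <- matrix(0L, n, len)
    par[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (len > 1L) {
      r <- .haldane_r(diff(map$cM[idx]))
      for (j in 2:len)
        par[, j] <- (par[, j - 1L] + stats::rbinom(n, 1L, r[j - 1L])) %% 2L
    }
    useB[, idx] <- par
  }
  out <- hapA
  pick <- useB == 1L
  out[pick] <- hapB[pick]
  out
}

# Survival probability of each candidate male gamete (row), given the parent
# sporophyte haplotypes. Activation is evaluated on the parent, not the
# gamete; collateral_c is a phenotype-only parameter and is ignored here.
# Loci absent from the map are untracked: a system whose killer locus is
# untracked cannot distort any tracked locus and is skipped; an untracked
# partner locus is held at its F1 heterozygous state (so an activator keeps
# the killer unconditionally active, a suppressor keeps it off).
.gamete_survival <- function(gam, hapA, hapB, map, systems) {
  surv <- rep(1, nrow(gam))
  for (sys in systems) {
    ki <- match(sys$killer$name, map$marker)
    pi <- match(sys$partner$name, map$marker)
    if (is.na(ki)) next
    het <- hapA[, ki] != hapB[, ki]
    pg <- if (is.na(pi)) rep("H", nrow(gam)) else .geno_codes(hapA[, pi], hapB[, pi])
    active <- het & (
      if (sys$partner_mode == "activator") pg %in% c("H", "II") else pg == "JJ"
    )
    hit <- active & gam[, ki] == sys$targeted_allele
    surv[hit] <- surv[hit] * sys$survival_s
  }
  surv
}

# Vectorised meiosis for n parents given as two n x L haplotype matrices.
# Male gametes undergo rejection sampling against the killer systems.
.meiosis <- function(hapA, hapB, map, systems = list(),
                     sex = c("male", "female"), max_rounds = 10000L) {
  sex <- match.arg(sex)
  gam <- .recombine(hapA, hapB, map)
  if (sex == "male" && length(systems)) {
    surv <- .gamete_survival(gam, hapA, hapB, map, systems)
    redo <- which(stats::runif(nrow(gam)) > surv)
    rounds <- 0L
    while (length(redo)) {
      rounds <- rounds + 1L
      if (rounds > max_rounds)
        stop("no surviving male gamete after ", max_rounds,
             " rounds of rejection sampling")
      g2 <- .recombine(hapA[redo, , drop = FALSE], hapB[redo, , drop = FALSE], map)
      s2 <- .gamete_survival(g2, hapA[redo, , drop = FALSE],
                             hapB[redo, , drop = FALSE], map, systems)
      keep <- stats::runif(length(redo)) <= s2
      gam[redo[keep], ] <- g2[keep, , drop = FALSE]
      redo <- redo[!keep]
    }
  }
  gam
}

#' A diploid individual as a pair of haplotypes
#'
#' @param hapA,hapB Character vectors of alleles (`"I"`/`"J"`), one entry per
#'   map locus, in map order.
#' @param map The [genetic_map()] the haplotypes refer to.
#' @return An object of class `individual`.
#' @export
individual <- function(hapA, hapB, map) {
  stopifnot(inherits(map, "genetic_map"),
            length(hapA) == nrow(map), length(hapB) == nrow(map))
  if (!all(c(hapA, hapB) %in% c("I", "J")))
    stop("haplotype alleles must be 'I' or 'J'")
  structure(list(hapA = stats::setNames(hapA, map$marker),
                 hapB = stats::setNames(hapB, map$marker)),
            class = "individual")
}

#' F1 hybrid individual (one I haplotype, one J haplotype)
#'
#' @param map A [genetic_map()].
#' @return An [individual()].
#' @export
f1_individual <- function(map) {
  individual(rep("I", nrow(map)), rep("J", nrow(map)), map)
}

#' Draw one gamete from a parent
#'
#' Recombination uses the Haldane map function between adjacent loci. For
#' `sex = "male"`, candidate gametes carrying a targeted allele at an active
#' killer locus are discarded with probability `1 - survival_s` and
#' redrawn (rejection sampling); activation is evaluated on the parent
#' sporophyte, never on the gamete itself.
#'
#' @param parent An [individual()].
#' @param map A [genetic_map()].
#' @param systems List of [killer_system()] objects.
#' @param sex `"male"` or `"female"`.
#' @return Named character vector of alleles, one per map locus.
#' @export
make_gamete <- function(parent, map, systems = list(), sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(parent, "individual"))
  if (inherits(systems, "killer_system")) systems <- list(systems)
  g <- .meiosis(matrix(parent$hapA, 1L), matrix(parent$hapB, 1L),
                map, systems, sex)
  stats::setNames(drop(g), map$marker)
}

.as_genotype_table <- function(hapA, hapB, map, prefix = "S") {
  codes <- .geno_codes(hapA, hapB)
  df <- data.frame(sample_id = sprintf("%s%04d", prefix, seq_len(nrow(hapA))),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(codes))) df[[map$marker[j]]] <- codes[, j]
  genotype_table(df)
}

#' Simulate a population under a cross design
#'
#' Founders are the homozygous donor (I) and recurrent (J) lines; all
#' designs start from their F1. `F2` selfs the F1; `testcross`/`backcross`
#' cross the F1 to the recurrent homozygote (killing acts only when the F1
#' is the male parent); `SSD_RI` propagates one selfed offspring per line
#' per generation.
#'
#' Loci absent from the map are untracked: a killer system whose killer
#' locus is untracked is skipped, and an untracked partner locus is held at
#' its F1 heterozygous state. Putting only the killer locus on the map
#' therefore simulates a killer held unconditionally active (the activator
#' fixed with a donor allele), matching the single-locus closed forms of
#' [selfing_freq()] and [ssd_freq()]; putting the partner on the map as well
#' lets activation segregate, which is what produces pseudo-linkage.
#'
#' @param design A [cross_design()].
#' @param map A [genetic_map()].
#' @param systems List of [killer_system()] objects (may be empty for
#'   neutral Mendelian inheritance).
#' @return A [genotype_table()] with `design$n` rows and one column per map
#'   locus.
#' @examples
#' map <- genetic_map(c("S35", "INK"), c("chr1", "chr5"), c(10, 25))
#' sys <- killer_system(locus("S35", "chr1", 3060000), locus("INK", "chr5", 1300000),
#'                      "activator", "J", survival_s = survival_s(0.89))
#' tab <- simulate_population(cross_design("F2", 200, seed = 1), map, list(sys))
#' table(tab$S35)
#' @export
simulate_population <- function(design, map, systems = list()) {
  stopifnot(inherits(design, "cross_design"), inherits(map, "genetic_map"))
  if (inherits(systems, "killer_system")) systems <- list(systems)
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n
  L <- nrow(map)
  f1A <- matrix("I", n, L)
  f1B <- matrix("J", n, L)
  if (design$type == "F2") {
    m <- .meiosis(f1A, f1B, map, systems, "male")
    f <- .meiosis(f1A, f1B, map, systems, "female")
    return(.as_genotype_table(m, f, map, "F2_"))
  }
  if (design$type %in% c("testcross", "backcross")) {
    rec <- matrix(design$recurrent_allele, n, L)
    if (design$het_parent == "male") {
      m <- .meiosis(f1A, f1B, map, systems, "male")
      return(.as_genotype_table(m, rec, map, "TC_"))
    }
    f <- .meiosis(f1A, f1B, map, systems, "female")
    return(.as_genotype_table(rec, f, map, "TC_"))
  }
  # SSD_RI: each line is an independent pedigree; selfing is vectorised
  # across lines within each generation.
  hapA <- f1A
  hapB <- f1B
  for (g in seq_len(design$generations)) {
    m <- .meiosis(hapA, hapB, map, systems, "male")
    f <- .meiosis(hapA, hapB, map, systems, "female")
    hapA <- m
    hapB <- f
  }
  .as_genotype_table(hapA, hapB, map, "RI_")
}

#' Two-locus association (pseudo-linkage) statistic
#'
#' Over the two-locus homozygous classes, parental combinations are
#' `(II, II)` and `(JJ, JJ)`, recombinant combinations `(II, JJ)` and
#' `(JJ, II)`. The parental-excess statistic
#' `(n_parental - n_recombinant) / (n_parental + n_recombinant)` is 0 for
#' free recombination, 1 for complete (pseudo-)linkage, and positive when
#' gametic selection on interacting alleles suppresses recombinant classes
#' between physically unlinked loci. A Pearson chi-square test of
#' independence on the 2x2 homozygous-class table is attached.
#'
#' @param table A [genotype_table()].
#' @param locusA,locusB Marker column names.
#' @return An object of class `two_locus_assoc` with `statistic`,
#'   `n_parental`, `n_recombinant`, `chisq`, `df`, `p_value`.
#' @export
two_locus_association <- function(table, locusA, locusB) {
  stopifnot(inherits(table, "genotype_table"))
  for (loc in c(locusA, locusB))
    if (!loc %in% names(table)) stop("locus '", loc, "' is not in the table")
  a <- table[[locusA]]
  b <- table[[locusB]]
  hom <- !is.na(a) & !is.na(b) & a %in% c("II", "JJ") & b %in% c("II", "JJ")
  a <- a[hom]; b <- b[hom]
  if (length(a) < 2L) stop("fewer than 2 informative (double-homozygous) lines")
  n_par <- sum(a == b)
  n_rec <- sum(a != b)
  statistic <- (n_par - n_rec) / (n_par + n_rec)
  tab <- matrix(c(sum(a == "II" & b == "II"), sum(a == "II" & b == "JJ"),
                  sum(a == "JJ" & b == "II"), sum(a == "JJ" & b == "JJ")),
                2L, 2L, byrow = TRUE)
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  expd <- outer(rs, cs) / tot
  chisq <- if (any(expd == 0)) NA_real_ else sum((tab - expd)^2 / expd)
  p_value <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, 1L, lower.tail = FALSE)
  structure(
    list(statistic = statistic, n_parental = n_par, n_recombinant = n_rec,
         chisq = chisq, df = 1L, p_value = p_value,
         loci = c(locusA, locusB)),
    class = "two_locus_assoc"
  )
}

#' @export
print.two_locus_assoc <- function(x, ...) {
  cat(sprintf("<two-locus association> %s x %s\n", x$loci[1], x$loci[2]))
  cat(sprintf("  parental %d : recombinant %d  excess = %.4f\n",
              x$n_parental, x$n_recombinant, x$statistic))
  if (!is.na(x$chisq))
    cat(sprintf("  independence X^2 = %.3f (df = %d), p = %.3g\n",
                x$chisq, x$df, x$p_value))
  invisible(x)
}
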