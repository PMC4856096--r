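# Core domain types: loci, killer systems, sporophyte genotypes, gamete
# distributions, and the activation rule that gates gamete killing.

GENOTYPE_CODES <- c("II", "H", "JJ")
LOCUS_ROLES <- c("killer", "partner", "neutral_marker")

#' Define a genetic locus
#'
#' A locus is a named position on a chromosome with a role in the killer
#' system: a gametophytic `killer` locus, a sporophytic `partner` locus
#' (activator or suppressor of a killer), or a `neutral_marker`.
#'
#' @param name Locus identifier (e.g. `"S35"`, `"INK"`, `"1c300"`).
#' @param chrom Chromosome label.
#' @param pos_bp 1-based physical position in base pairs; must be positive.
#' @param role One of `"killer"`, `"partner"`, `"neutral_marker"`.
#' @return An object of class `locus_def`.
#' @examples
#' locus("S35", "chr1", 3060000, "killer")
#' @export
locus <- function(name, chrom, pos_bp, role = "neutral_marker") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, LOCUS_ROLES)
  pos_bp <- as.integer(pos_bp)
  if (is.na(pos_bp) || pos_bp <= 0L)
    stop("pos_bp must be a positive integer for locus '", name, "'")
  structure(
    list(name = name, chrom = as.character(chrom), pos_bp = pos_bp, role = role),
    class = "locus_def"
  )
}

#' @export
print.locus_def <- function(x, ...) {
  cat(sprintf("<locus> %s  %s:%d  [%s]\n", x$name, x$chrom, x$pos_bp, x$role))
  invisible(x)
}

#' Convert between survival s and transmission parameter k
#'
#' A heterozygous killer kills each targeted male gamete with probability
#' `1 - s` (so `s` is the survival probability of a targeted gamete). The
#' surviving pollen pool then carries the favoured (killer) allele with
#' probability `k = 1 / (1 + s)`. `s = 1` gives Mendelian transmission
#' (`k = 0.5`); `s = 0` gives complete killing (`k = 1`).
#'
#' @param s Survival probability of a targeted gamete, in `[0, 1]`.
#' @param k Transmission probability of the favoured allele, in `(0, 1]`.
#' @return `transmission_k()` returns k; `survival_s()` returns s.
#' @examples
#' transmission_k(0.1236) # ~0.89
#' survival_s(0.89)       # ~0.1236
#' @export
transmission_k <- function(s) {
  stopifnot(is.numeric(s), all(s >= 0 & s <= 1))
  1 / (1 + s)
}

#' @rdname transmission_k
#' @export
survival_s <- function(k) {
  stopifnot(is.numeric(k), all(k > 0 & k <= 1))
  1 / k - 1
}

#' Define a pollen-killer system
#'
#' Pairs one gametophytic killer locus with its sporophytic partner locus.
#' The partner's donor (I) allele either dominantly activates the killer
#' (`partner_mode = "activator"`) or dominantly suppresses it
#' (`partner_mode = "suppressor"`). Killing acts on the male side only: in a
#' sporophyte heterozygous at the killer locus, pollen carrying
#' `targeted_allele` survives with probability `survival_s`; the rest of the
#' pollen suffers an optional collateral death rate `collateral_c` that
#' affects pollen-fertility phenotypes but never transmission ratios.
#'
#' @param killer,partner [locus()] objects (roles are set to killer/partner).
#' @param partner_mode `"activator"` or `"suppressor"`.
#' @param targeted_allele Which allele's pollen is killed, `"I"` or `"J"`.
#' @param survival_s Probability a targeted male gamete survives, in `[0, 1]`.
#' @param collateral_c Death rate of non-targeted pollen, in `[0, 1]`; default 0.
#' @return An object of class `killer_system` with derived transmission
#'   parameter `k = 1/(1 + survival_s)` stored in `$k`.
#' @examples
#' killer_system(
#'   killer = locus("S35", "chr1", 3060000, "killer"),
#'   partner = locus("INK", "chr5", 1300000, "partner"),
#'   partner_mode = "activator", targeted_allele = "J",
#'   survival_s = survival_s(0.89)
#' )
#' @export
killer_system <- function(killer, partner, partner_mode, targeted_allele,
                          survival_s, collateral_c = 0) {
  stopifnot(inherits(killer, "locus_def"), inherits(partner, "locus_def"))
  partner_mode <- match.arg(partner_mode, c("activator", "suppressor"))
  targeted_allele <- match.arg(targeted_allele, c("I", "J"))
  if (!is.numeric(survival_s) || length(survival_s) != 1L ||
      survival_s < 0 || survival_s > 1)
    stop("survival_s must be a single number in [0, 1]")
  if (!is.numeric(collateral_c) || length(collateral_c) != 1L ||
      collateral_c < 0 || collateral_c > 1)
    stop("collateral_c must be a single number in [0, 1]")
  killer$role <- "killer"
  partner$role <- "partner"
  structure(
    list(
      killer = killer, partner = partner,
      partner_mode = partner_mode, targeted_allele = targeted_allele,
      survival_s = survival_s, collateral_c = collateral_c,
      k = 1 / (1 + survival_s), sex_limited = "male"
    ),
    class = "killer_system"
  )
}

#' @export
print.killer_system <- function(x, ...) {
  cat(sprintf(
    "<killer system> %s (targets %s pollen) gated by %s [%s]\n  s = %.4f, c = %.3f, k = %.4f\n",
    x$killer$name, x$targeted_allele, x$partner$name, x$partner_mode,
    x$survival_s, x$collateral_c, x$k
  ))
  invisible(x)
}

#' Sporophyte (diploid plant) genotype
#'
#' A mapping from locus names to genotype codes `II`, `H`, `JJ` (I = donor /
#' indica allele, J = recurrent / japonica allele). Missing codes are not
#' permitted in model inputs.
#'
#' @param ... Named genotype codes, e.g. `S35 = "H", INK = "II"`, or a single
#'   named character vector.
#' @return An object of class `sporophyte`.
#' @examples
#' sporophyte(S35 = "H", INK = "H", S24 = "JJ", EFS = "JJ")
#' @export
sporophyte <- function(...) {
  g <- c(...)
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("all genotype entries must be named by locus")
  if (anyNA(g))
    stop("NA genotype codes are not permitted in a sporophyte")
  bad <- setdiff(unique(g), GENOTYPE_CODES)
  if (length(bad))
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "),
         " (expected II, H, JJ)")
  if (anyDuplicated(names(g)))
    stop("duplicated locus name in sporophyte genotype")
  structure(g, class = "sporophyte")
}

#' @export
print.sporophyte <- function(x, ...) {
  cat("<sporophyte>", paste(names(x), unclass(x), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.sporophyte_code <- function(sporophyte, locus_name) {
  if (!locus_name %in% names(sporophyte))
    stop("locus '", locus_name, "' is not present in the sporophyte genotype")
  code <- unclass(sporophyte)[[locus_name]]
  if (is.na(code)) stop("genotype at locus '", locus_name, "' is NA")
  code
}

#' Is a killer system active in a given sporophyte?
#'
#' The killer acts only when the sporophyte is heterozygous at the killer
#' locus (homozygotes have no targeted-vs-nontargeted pollen contrast and are
#' defined inactive) and the sporophytic partner condition holds: an
#' activator requires at least one donor allele (`H` or `II`), a suppressor
#' requires the absence of the donor allele (`JJ`). Partner dominance is
#' complete; there is no dosage effect.
#'
#' @param system A [killer_system()].
#' @param sporophyte A [sporophyte()] covering the system's killer and
#'   partner loci.
#' @return Logical scalar.
#' @examples
#' sys <- killer_system(locus("S35", "chr1", 3060000), locus("INK", "chr5", 1300000),
#'                      "activator", "J", survival_s = 0.1236)
#' killer_is_active(sys, sporophyte(S35 = "H", INK = "H"))  # TRUE
#' killer_is_active(sys, sporophyte(S35 = "H", INK = "JJ")) # FALSE
#' @export
killer_is_active <- function(system, sporophyte) {
  stopifnot(inherits(system, "killer_system"))
  kg <- .sporophyte_code(sporophyte, system$killer$name)
  pg <- .sporophyte_code(sporophyte, system$partner$name)
  if (kg != "H") return(FALSE)
  if (system$partner_mode == "activator") pg %in% c("H", "II") else pg == "JJ"
}

#' Gamete allele distribution
#'
#' @param probs Named numeric vector of allele (or haplotype) probabilities;
#'   must be non-negative and sum to 1 within 1e-12.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `gamete_distribution`.
#' @export
gamete_distribution <- function(probs, sex) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.numeric(probs), !is.null(names(probs)))
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("gamete probabilities must be non-negative and sum to 1")
  structure(list(probs = probs, sex = sex), class = "gamete_distribution")
}

#' @export
print.gamete_distribution <- function(x, ...) {
  cat(sprintf("<%s gamete distribution> %s\n", x$sex,
              paste(sprintf("P(%s)=%.4g", names(x$probs), x$probs), collapse = ", ")))
  invisible(x)
}

#' Male gamete transmission distribution at one locus
#'
#' For a sporophyte heterozygous at the killer locus of an active system, the
#' surviving male gamete pool carries the targeted allele with probability
#' `s/(1+s)` and the favoured allele with probability `k = 1/(1+s)`. A
#' heterozygous non-killer locus (or an inactive killer) transmits 0.5/0.5;
#' a homozygous locus gives a degenerate distribution. Multiple active
#' systems sharing the same killer locus compose multiplicatively on
#' survival weights.
#'
#' @param sporophyte A [sporophyte()].
#' @param systems A list of [killer_system()] objects (may be empty).
#' @param locus A [locus()] or a locus name present in the sporophyte.
#' @return A [gamete_distribution()] over alleles `I` and `J`.
#' @examples
#' sys <- killer_system(locus("S35", "chr1", 3060000), locus("INK", "chr5", 1300000),
#'                      "activator", "J", survival_s = 0.1236)
#' male_gamete_distribution(sporophyte(S35 = "H", INK = "H"), list(sys), "S35")
#' @export
male_gamete_distribution <- function(sporophyte, systems, locus) {
  locus_name <- if (inherits(locus, "locus_def")) locus$name else as.character(locus)
  code <- .sporophyte_code(sporophyte, locus_name)
  if (code == "II") return(gamete_distribution(c(I = 1, J = 0), "male"))
  if (code == "JJ") return(gamete_distribution(c(I = 0, J = 1), "male"))
  if (inherits(systems, "killer_system")) systems <- list(systems)
  w <- c(I = 1, J = 1) # survival weights per allele class
  for (sys in systems) {
    if (sys$killer$name != locus_name) next
    if (!killer_is_active(sys, sporophyte)) next
    w[sys$targeted_allele] <- w[sys$targeted_allele] * sys$survival_s
  }
  gamete_distribution(w / sum(w), "male")
}

#' Female gamete transmission distribution at one locus
#'
#' Gamete killing is male-limited, so female transmission is always
#' Mendelian: a heterozygote transmits 0.5/0.5 regardless of any active
#' killer system, and a homozygote gives a degenerate distribution.
#'
#' @inheritParams male_gamete_distribution
#' @return A [gamete_distribution()] over alleles `I` and `J`.
#' @export
female_gamete_distribution <- function(sporophyte, locus) {
  locus_name <- if (inherits(locus, "locus_def")) locus$name else as.character(locus)
  code <- .sporophyte_code(sporophyte, locus_name)
  probs <- switch(code,
    II = c(I = 1, J = 0),
    JJ = c(I = 0, J = 1),
    H  = c(I = 0.5, J = 0.5)
  )
  gamete_distribution(probs, "female")
}
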