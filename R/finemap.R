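# Deterministic breakpoint fine mapping: intersect per-line admissible
# regions implied by recombinant marker genotypes and carrier/noncarrier
# phenotypes to obtain the minimal candidate interval for a causal locus.

#' Recombinant panel for breakpoint fine mapping
#'
#' @param map Data frame (or [genetic_map()]) with columns `marker`,
#'   `chrom`, `pos_bp`; all markers on one chromosome, at least two,
#'   sorted (or sortable) by `pos_bp`.
#' @param genotypes Data frame or matrix of genotype codes (`II`, `H`, `JJ`,
#'   `NA`), lines x markers, columns named by marker.
#' @param phenotype Character/factor per line: `"carrier"` (shows the
#'   causal-locus phenotype) or `"noncarrier"`.
#' @param line_id Optional line identifiers; default `L001`, ...
#' @return An object of class `recombinant_panel`.
#' @export
recombinant_panel <- function(map, genotypes, phenotype, line_id = NULL) {
  stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(map)))
  if (length(unique(map$chrom)) != 1L)
    stop("all panel markers must lie on one chromosome")
  if (nrow(map) < 2L) stop("a panel needs at least two markers")
  ord <- order(map$pos_bp)
  map <- map[ord, , drop = FALSE]
  if (anyDuplicated(map$pos_bp)) stop("marker positions must be distinct")
  genotypes <- as.matrix(genotypes)[, map$marker, drop = FALSE]
  storage.mode(genotypes) <- "character"
  bad <- !(genotypes %in% GENOTYPE_CODES | is.na(genotypes))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("unknown genotype code '", genotypes[w[1], w[2]], "' at line ", w[1],
         ", marker '", colnames(genotypes)[w[2]], "'")
  }
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% c("carrier", "noncarrier")))
    stop("phenotype must be 'carrier' or 'noncarrier'")
  if (length(phenotype) != nrow(genotypes))
    stop("one phenotype per line required")
  if (is.null(line_id)) line_id <- sprintf("L%03d", seq_len(nrow(genotypes)))
  rownames(genotypes) <- line_id
  structure(list(map = map, genotypes = genotypes, phenotype = phenotype,
                 line_id = line_id),
            class = "recombinant_panel")
}

#' @export
print.recombinant_panel <- function(x, ...) {
  cat(sprintf("<recombinant panel> %d lines x %d markers on %s (%s..%s bp)\n",
              nrow(x$genotypes), nrow(x$map), x$map$chrom[1],
              format(min(x$map$pos_bp), big.mark = ","),
              format(max(x$map$pos_bp), big.mark = ",")))
  invisible(x)
}

# Carrier predicate on genotype codes. Dominant donor factors (e.g. an
# activator): H or II carries the phenotype. Gametophytic killers show the
# phenotype only in heterozygotes. Recessive donor factors require II.
.carrier_predicate <- function(carrier_rule) {
  switch(carrier_rule,
    "dominant-donor" = function(g) ifelse(is.na(g), NA, g == "H" | g == "II"),
    "het" = function(g) g == "H",
    "recessive-donor" = function(g) g == "II",
    stop("unknown carrier_rule '", carrier_rule,
         "' (use 'dominant-donor', 'het', or 'recessive-donor')")
  )
}

# Per-line admissibility over the extended candidate positions: markers
# (odd extended indices 1, 3, ...) interleaved with inter-marker gaps (even
# indices). A marker constrains directly through its genotype; the interior
# of a gap is constrained by the flanking non-NA genotypes when both imply
# the same carrier state, and is unconstrained across a genotype transition
# (the line's breakpoint may fall anywhere inside it). NA genotypes impose
# no constraint.
.admissible_ext <- function(genotypes, phenotype, is_carrier_geno) {
  n <- nrow(genotypes); L <- ncol(genotypes)
  obs <- phenotype == "carrier"
  pred_m <- matrix(is_carrier_geno(genotypes), n, L) # NA stays NA
  adm <- matrix(TRUE, n, 2L * L - 1L)
  adm[, seq(1L, 2L * L - 1L, by = 2L)] <- is.na(pred_m) | pred_m == obs
  if (L > 1L) {
    for (j in seq_len(L - 1L)) {
      gap_pred <- rep(NA, n)
      for (i in seq_len(n)) {
        left <- pred_m[i, seq_len(j)]
        right <- pred_m[i, (j + 1L):L]
        gl <- if (any(!is.na(left))) left[max(which(!is.na(left)))] else NA
        gr <- if (any(!is.na(right))) right[min(which(!is.na(right)))] else NA
        if (!is.na(gl) && !is.na(gr) && gl == gr) gap_pred[i] <- gl
      }
      adm[, 2L * j] <- is.na(gap_pred) | gap_pred == obs
    }
  }
  adm
}

#' Infer the candidate interval for a causal locus from a recombinant panel
#'
#' For each line, the causal locus must lie where the line's genotype
#' predicts its phenotype under `carrier_rule`. Candidate positions are the
#' markers themselves plus the inter-marker gaps: a gap across a genotype
#' transition imposes no constraint (the breakpoint may fall on either side
#' of the causal locus within it), while a gap flanked by genotypes of equal
#' carrier state inherits that state. `NA` genotypes impose no constraint.
#' The admissible region is the intersection over lines, reported as the
#' open interval between the closest flanking contradicted markers (or the
#' outermost panel markers when no contradiction flanks a side). An empty
#' intersection signals a phenotyping error or a second locus and raises an
#' error naming the conflicting lines.
#'
#' @param panel A [recombinant_panel()].
#' @param carrier_rule `"dominant-donor"` (carrier iff `H` or `II`),
#'   `"het"` (carrier iff `H`; gametophytic killers), or
#'   `"recessive-donor"` (carrier iff `II`).
#' @return An object of class `candidate_interval` with flanking markers and
#'   positions, `length_bp`, the admissible marker names, and the admissible
#'   extended regions (`admissible_regions`, gap labels like `"(m03,m04)"`).
#' @examples
#' map <- data.frame(marker = paste0("m", 1:5), chrom = "chr1",
#'                   pos_bp = 1:5 * 1000000L)
#' g <- rbind(c("II", "II", "II", "JJ", "JJ"),
#'            c("JJ", "JJ", "JJ", "II", "II"))
#' colnames(g) <- map$marker
#' pan <- recombinant_panel(map, g, c("carrier", "noncarrier"))
#' infer_interval(pan, "dominant-donor")
#' @export
infer_interval <- function(panel, carrier_rule = "dominant-donor") {
  stopifnot(inherits(panel, "recombinant_panel"))
  is_carrier_geno <- .carrier_predicate(carrier_rule)
  g <- panel$genotypes
  L <- ncol(g)
  adm_by_line <- .admissible_ext(g, panel$phenotype, is_carrier_geno)
  admissible <- apply(adm_by_line, 2L, all)
  if (!any(admissible)) {
    # a line conflicts if it excludes a position that all other lines admit
    conflicting <- vapply(seq_len(nrow(g)), function(i) {
      others <- apply(adm_by_line[-i, , drop = FALSE], 2L, all)
      any(others & !adm_by_line[i, ])
    }, logical(1))
    if (!any(conflicting)) conflicting <- rep(TRUE, nrow(g))
    stop("no candidate position is consistent with all lines; conflicting lines: ",
         paste(panel$line_id[conflicting], collapse = ", "),
         " (phenotyping error or a second causal locus?)")
  }
  m <- panel$map
  ext_labels <- character(2L * L - 1L)
  ext_labels[seq(1L, 2L * L - 1L, 2L)] <- m$marker
  if (L > 1L)
    ext_labels[seq(2L, 2L * L - 2L, 2L)] <-
      sprintf("(%s,%s)", m$marker[-L], m$marker[-1L])
  idx <- which(admissible)
  lo <- min(idx); hi <- max(idx)
  marker_ext <- seq(1L, 2L * L - 1L, 2L)
  bad_marker <- marker_ext[!admissible[marker_ext]]
  left_i <- if (any(bad_marker < lo)) (max(bad_marker[bad_marker < lo]) + 1L) %/% 2L else 1L
  right_i <- if (any(bad_marker > hi)) (min(bad_marker[bad_marker > hi]) + 1L) %/% 2L else L
  structure(
    list(
      left_marker = m$marker[left_i], right_marker = m$marker[right_i],
      left_bp = m$pos_bp[left_i], right_bp = m$pos_bp[right_i],
      length_bp = m$pos_bp[right_i] - m$pos_bp[left_i],
      chrom = m$chrom[1],
      admissible_markers = m$marker[admissible[marker_ext]],
      admissible_regions = ext_labels[idx],
      carrier_rule = carrier_rule,
      n_lines = nrow(g)
    ),
    class = "candidate_interval"
  )
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf("<candidate interval> %s: (%s @ %s bp, %s @ %s bp), length %s bp\n",
              x$chrom, x$left_marker, format(x$left_bp, big.mark = ","),
              x$right_marker, format(x$right_bp, big.mark = ","),
              format(x$length_bp, big.mark = ",")))
  cat("  admissible regions:", paste(x$admissible_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Report a candidate interval
#'
#' Summarises the interval with flanking markers, base-pair length and
#' per-line support (how many markers each line excludes). The list
#' round-trips losslessly through JSON.
#'
#' @param interval A `candidate_interval` from [infer_interval()].
#' @param panel The [recombinant_panel()] it was computed from.
#' @return A list (class `interval_report`) suitable for
#'   `jsonlite::toJSON()`.
#' @export
interval_report <- function(interval, panel) {
  stopifnot(inherits(interval, "candidate_interval"),
            inherits(panel, "recombinant_panel"))
  is_carrier_geno <- .carrier_predicate(interval$carrier_rule)
  obs <- panel$phenotype == "carrier"
  pred <- matrix(is_carrier_geno(panel$genotypes),
                 nrow(panel$genotypes), ncol(panel$genotypes))
  excluded <- rowSums(!(is.na(pred) | pred == obs))
  structure(
    list(
      chrom = interval$chrom,
      left_marker = interval$left_marker, left_bp = interval$left_bp,
      right_marker = interval$right_marker, right_bp = interval$right_bp,
      length_bp = interval$length_bp,
      admissible_markers = interval$admissible_markers,
      admissible_regions = interval$admissible_regions,
      carrier_rule = interval$carrier_rule,
      lines = data.frame(line_id = panel$line_id,
                         phenotype = panel$phenotype,
                         n_markers_excluded = as.integer(excluded),
                         stringsAsFactors = FALSE)
    ),
    class = "interval_report"
  )
}

#' @export
print.interval_report <- function(x, ...) {
  cat(sprintf("Candidate interval on %s between %s and %s: %s bp\n",
              x$chrom, x$left_marker, x$right_marker,
              format(x$length_bp, big.mark = ",")))
  cat(sprintf("Informative lines: %d of %d exclude at least one marker\n",
              sum(x$lines$n_markers_excluded > 0), nrow(x$lines)))
  invisible(x)
}
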