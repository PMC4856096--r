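mk_panel <- function(geno_rows, phen, pos = seq_along(geno_rows[[1]]) * 1000000L,
                     markers = sprintf("m%d", seq_along(pos))) {
  g <- do.call(rbind, geno_rows)
  colnames(g) <- markers
  map <- data.frame(marker = markers, chrom = "chr1", pos_bp = as.integer(pos),
                    stringsAsFactors = FALSE)
  recombinant_panel(map, g, phen)
}

test_that("breakpoint intersection narrows the candidate interval", {
  # line A: donor on markers 1-3, carrier -> locus within donor segment
  # line B: donor on markers 4-5, noncarrier -> locus not in markers 4-5
  pan <- mk_panel(list(c("II", "II", "II", "JJ", "JJ"),
                       c("JJ", "JJ", "JJ", "II", "II")),
                  c("carrier", "noncarrier"))
  iv <- infer_interval(pan, "dominant-donor")
  expect_equal(iv$admissible_markers, c("m1", "m2", "m3"))
  expect_equal(iv$right_marker, "m4") # closest contradicted marker on the right
  expect_equal(iv$left_marker, "m1")  # no contradiction to the left
  # an extra noncarrier line donor on 1-2 trims the left side
  pan2 <- mk_panel(list(c("II", "II", "II", "JJ", "JJ"),
                        c("JJ", "JJ", "JJ", "II", "II"),
                        c("II", "II", "JJ", "JJ", "JJ")),
                   c("carrier", "noncarrier", "noncarrier"))
  iv2 <- infer_interval(pan2, "dominant-donor")
  expect_equal(iv2$admissible_markers, "m3")
  expect_equal(iv2$left_marker, "m2")
  expect_equal(iv2$right_marker, "m4")
  expect_equal(iv2$length_bp, 2000000L)
})

test_that("a single uninformative line yields the whole panel span", {
  pan <- mk_panel(list(c("II", "II", "II", "II", "II")), "carrier")
  iv <- infer_interval(pan, "dominant-donor")
  expect_equal(iv$left_marker, "m1")
  expect_equal(iv$right_marker, "m5")
  expect_equal(iv$length_bp, 4000000L)
})

test_that("contradictory lines raise an inconsistency error naming them", {
  # an all-donor noncarrier line is individually inconsistent and is named
  pan <- mk_panel(list(c("II", "II", "II"), c("II", "II", "II")),
                  c("carrier", "noncarrier"))
  expect_error(infer_interval(pan, "dominant-donor"), "L002")
  # a jointly (but not individually) inconsistent pair names both lines
  pan2 <- mk_panel(list(c("II", "JJ", "JJ"), c("II", "II", "JJ")),
                   c("carrier", "noncarrier"))
  expect_error(infer_interval(pan2, "dominant-donor"), "L001, L002")
})

test_that("NA genotypes impose no constraint", {
  pan <- mk_panel(list(c("II", NA, "JJ"), c(NA, "JJ", "JJ")),
                  c("carrier", "noncarrier"))
  iv <- infer_interval(pan, "dominant-donor")
  expect_equal(iv$admissible_markers, c("m1", "m2"))
})

test_that("carrier rules select the correct genotype predicate", {
  # gametophytic rule: only H is a carrier genotype
  pan <- mk_panel(list(c("II", "H", "JJ")), "carrier")
  expect_equal(infer_interval(pan, "het")$admissible_markers, "m2")
  expect_equal(infer_interval(pan, "recessive-donor")$admissible_markers, "m1")
  expect_error(infer_interval(pan, "additive"), "carrier_rule")
})

test_that("interval length mirrors physical marker spacing", {
  pan <- mk_panel(list(c("II", "JJ"), c("JJ", "II")),
                  c("carrier", "noncarrier"),
                  pos = c(3000000L, 3122000L), markers = c("1c300", "1c312"))
  iv <- infer_interval(pan, "dominant-donor")
  expect_equal(iv$length_bp, 122000L)
  expect_true(iv$left_bp < iv$right_bp)
})

test_that("infer_interval agrees with the brute-force per-position oracle", {
  set.seed(31)
  for (rep in 1:200) {
    rule <- sample(c("dominant-donor", "het", "recessive-donor"), 1)
    g <- gen_recombinant_panel(sample(3:12, 1), sample(2:30, 1),
                               causal_pos = runif(1, 1.05e6, 3.95e6),
                               carrier_rule = rule,
                               seed = sample.int(1e6, 1))
    iv <- infer_interval(g$panel, rule)
    ora <- oracle_admissible(g$panel, rule)
    L <- nrow(g$panel$map)
    impl <- logical(2L * L - 1L)
    labels <- character(2L * L - 1L)
    labels[seq(1, 2 * L - 1, 2)] <- g$panel$map$marker
    labels[seq_len(L - 1) * 2] <- sprintf("(%s,%s)", g$panel$map$marker[-L],
                                          g$panel$map$marker[-1])
    impl[match(iv$admissible_regions, labels)] <- TRUE
    expect_identical(impl, ora)
  }
})

test_that("adding an informative line never widens the interval", {
  set.seed(37)
  for (rep in 1:30) {
    g <- gen_recombinant_panel(8, 15, causal_pos = runif(1, 1.1e6, 3.9e6),
                               seed = sample.int(1e6, 1))
    prev <- infer_interval(subset_panel(g$panel, 1:2), g$truth$carrier_rule)
    for (n in 3:15) {
      cur <- infer_interval(subset_panel(g$panel, 1:n), g$truth$carrier_rule)
      expect_gte(cur$left_bp, prev$left_bp)
      expect_lte(cur$right_bp, prev$right_bp)
      prev <- cur
    }
  }
})

test_that("interval reports round-trip through JSON losslessly", {
  g <- gen_recombinant_panel(6, 10, causal_pos = 2000000, seed = 41)
  iv <- infer_interval(g$panel)
  rep <- interval_report(iv, g$panel)
  expect_equal(rep$length_bp, iv$right_bp - iv$left_bp)
  back <- jsonlite::fromJSON(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE,
                                              digits = NA))
  expect_equal(back$left_marker, rep$left_marker)
  expect_equal(back$right_bp, rep$right_bp)
  expect_equal(back$length_bp, rep$length_bp)
  expect_equal(back$lines$line_id, rep$lines$line_id)
  expect_equal(back$lines$n_markers_excluded, rep$lines$n_markers_excluded)
})

test_that("panel constructor validates structure", {
  map <- data.frame(marker = c("a", "b"), chrom = c("chr1", "chr2"),
                    pos_bp = c(1L, 2L))
  g <- matrix("II", 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(recombinant_panel(map, g, "carrier"), "one chromosome")
  map$chrom <- "chr1"
  expect_error(recombinant_panel(map, matrix("XX", 1, 2,
                                             dimnames = list(NULL, c("a", "b"))),
                                 "carrier"), "unknown genotype")
  expect_error(recombinant_panel(map, g, "sick"), "carrier")
})
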