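test_that("15-mer enumeration yields L-14 ordered windows", {
  expect_equal(nrow(enumerate_15mers(strrep("A", 15))), 1L)
  p20 <- paste(rep(c("A", "C", "D", "E"), 5), collapse = "")
  w <- enumerate_15mers(p20)
  expect_equal(nrow(w), 6L)
  expect_equal(w$start, 0:5)
  expect_equal(w$sequence[2], substr(p20, 2, 16))
  expect_equal(nrow(enumerate_15mers(strrep("A", 14))), 0L)
})

test_that("self-peptidome is a set union over configured self loci", {
  lib <- toy_allele_library()
  hom <- genotype(c("A*01:01", "A*01:01"), c("B*01:01", "B*01:01"),
                  c("DRB1*01:01", "DRB1*01:01"), lib)
  het_same <- genotype(c("A*01:01", "A*01:01"), c("B*01:01", "B*01:01"),
                       c("DRB1*01:01", "DRB1*02:01"), lib)
  s_hom <- self_peptidome(hom, lib)
  # homozygous = same set as one allele per locus; identical sequences add nothing
  one_each <- unique(unlist(lapply(
    lib$protein[match(c("A*01:01", "B*01:01", "DRB1*01:01"), lib$name)],
    function(p) enumerate_15mers(p)$sequence)))
  expect_setequal(s_hom, one_each)
  # restricting self loci shrinks (or keeps) the set
  expect_true(all(self_peptidome(hom, lib, self_loci = c("A", "B")) %in% s_hom))
  expect_gte(length(self_peptidome(het_same, lib)), length(s_hom))
})

test_that("PWM predictor scores windows, takes leftmost maximal core, thresholds", {
  pred <- w_counting_predictor("DRB1*01:01")
  # peptide with a single W at position 10: windows 2..7 contain it, window 2
  # (leftmost among maxima) is the core
  pep <- paste0(strrep("A", 9), "W", strrep("A", 5))
  call <- predict_presentation(pred, pep, "DRB1*01:01")
  expect_true(call$presented)
  expect_equal(call$core, substr(pep, 2, 10))
  expect_equal(call$affinity_score, 1)
  # no W anywhere: all windows below threshold
  call0 <- predict_presentation(pred, strrep("A", 15), "DRB1*01:01")
  expect_false(call0$presented)
  expect_true(is.na(call0$core))
  # missing PWM is an error
  expect_error(predict_presentation(pred, pep, "DRB1*09:09"), "DRB1\\*09:09")
})

test_that("identical genotypes score zero", {
  ref <- tiny_reference(301)
  set.seed(302)
  for (i in 1:10) {
    g <- random_genotype(ref$library)
    expect_equal(pirche_ii_score(g, g, ref$library, ref$predictor)$raw_score, 0L)
  }
})

test_that("identical cores are counted once per presenting DRB1 protein", {
  # donor A allele: a 16-residue protein whose two 15-mers both contain the
  # full 9xW run, so the predictor picks the same core in each
  motif <- paste0("A", strrep("W", 9), strrep("A", 6))  # length 16
  lib <- engineered_library(motif)
  pred <- w_counting_predictor(c("DRB1*01:01", "DRB1*02:01"))
  donor <- genotype(c("A*01:01", "A*01:01"), c("B*01:01", "B*01:01"),
                    c("DRB1*01:01", "DRB1*01:01"), lib)
  # recipient carries only blank proteins; one presenting DRB1 allele
  rec1 <- genotype(c("A*02:01", "A*02:01"), c("B*01:01", "B*01:01"),
                   c("DRB1*01:01", "DRB1*01:01"), lib)
  res1 <- pirche_ii_score(donor, rec1, lib, pred)
  # both donor 15-mers maximize at the same 9-W core: one (core, presenter)
  # pair despite two distinct presented peptides
  expect_equal(res1$raw_score, 1L)
  expect_equal(unique(res1$pairs$core), strrep("W", 9))

  # same core presented by two distinct recipient DRB1 alleles counts twice
  rec2 <- genotype(c("A*02:01", "A*02:01"), c("B*01:01", "B*01:01"),
                   c("DRB1*01:01", "DRB1*02:01"), lib)
  res2 <- pirche_ii_score(donor, rec2, lib, pred)
  expect_equal(res2$raw_score, 2L)
  expect_setequal(res2$pairs$presenter, c("DRB1*01:01", "DRB1*02:01"))
})

test_that("optimized score, naive oracle and cached scorer agree on random instances", {
  set.seed(777)
  for (rep in 1:6) {
    ref <- tiny_reference(1000 + rep, protein_length = sample(20:35, 1))
    scorer <- genotype_scorer(ref$library, ref$predictor)
    for (i in 1:15) {
      d <- random_genotype(ref$library)
      r <- random_genotype(ref$library)
      fast <- pirche_ii_score(d, r, ref$library, ref$predictor)$raw_score
      slow <- brute_force_score(d, r, ref$library, ref$predictor)
      expect_identical(fast, slow)
      expect_identical(as.integer(scorer(d, r)), fast)
    }
  }
})

test_that("score is monotone in self-peptidome and presenter set, and deterministic", {
  set.seed(888)
  ref <- tiny_reference(2024)
  lib <- ref$library
  for (i in 1:25) {
    d <- random_genotype(lib)
    r <- random_genotype(lib)
    # growing the self-peptidome can only remove countable peptides
    s_ab <- pirche_ii_score(d, r, lib, ref$predictor, self_loci = c("A", "B"))
    s_abd <- pirche_ii_score(d, r, lib, ref$predictor)
    expect_gte(s_ab$raw_score, s_abd$raw_score)
    # an extra presenting DRB1 allele can only add (core, presenter) pairs;
    # fix the self-peptidome to A+B so the presenter change is isolated
    drb1_pool <- lib$name[lib$locus == "DRB1"]
    r_hom <- genotype(r$A, r$B, rep(r$DRB1[1], 2), lib)
    r_het <- genotype(r$A, r$B, c(r$DRB1[1], sample(setdiff(drb1_pool, r$DRB1[1]), 1)), lib)
    one <- pirche_ii_score(d, r_hom, lib, ref$predictor, self_loci = c("A", "B"))
    two <- pirche_ii_score(d, r_het, lib, ref$predictor, self_loci = c("A", "B"))
    expect_gte(two$raw_score, one$raw_score)
    # determinism, including core choices
    again <- pirche_ii_score(d, r, lib, ref$predictor)
    expect_identical(again$pairs, s_abd$pairs)
  }
})

test_that("score is invariant to donor allele ordering and homozygous duplication", {
  set.seed(999)
  ref <- tiny_reference(3030)
  lib <- ref$library
  for (i in 1:10) {
    d <- random_genotype(lib)
    r <- random_genotype(lib)
    base <- pirche_ii_score(d, r, lib, ref$predictor)$raw_score
    d_rev <- genotype(rev(d$A), rev(d$B), rev(d$DRB1), lib)
    expect_identical(pirche_ii_score(d_rev, r, lib, ref$predictor)$raw_score, base)
  }
  # a second donor allele with an identical protein adds nothing: hom pair
  # and a synonym pair score alike
  motif <- paste0("AC", strrep("W", 9), strrep("A", 19))
  lib2 <- engineered_library(c(motif, motif))
  pred <- w_counting_predictor(c("DRB1*01:01", "DRB1*02:01"))
  rec <- genotype(c("A*03:01", "A*03:01"), c("B*01:01", "B*01:01"),
                  c("DRB1*01:01", "DRB1*01:01"), lib2)
  hom <- genotype(c("A*01:01", "A*01:01"), c("B*01:01", "B*01:01"),
                  c("DRB1*01:01", "DRB1*01:01"), lib2)
  syn <- genotype(c("A*01:01", "A*02:01"), c("B*01:01", "B*01:01"),
                  c("DRB1*01:01", "DRB1*01:01"), lib2)
  expect_identical(pirche_ii_score(hom, rec, lib2, pred)$raw_score,
                   pirche_ii_score(syn, rec, lib2, pred)$raw_score)
})

test_that("PWM configuration round-trips through YAML", {
  ref <- tiny_reference(4040)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pwm_config(ref$predictor, path)
  back <- read_pwm_config(path)
  expect_setequal(names(back$pwms), names(ref$predictor$pwms))
  pep <- substr(strrep(paste(ref$library$protein, collapse = ""), 1), 1, 15)
  for (al in names(back$pwms)) {
    expect_equal(back$pwms[[al]]$threshold, ref$predictor$pwms[[al]]$threshold,
                 tolerance = 1e-10)
    expect_equal(predict_presentation(back, pep, al),
                 predict_presentation(ref$predictor, pep, al))
  }
})
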