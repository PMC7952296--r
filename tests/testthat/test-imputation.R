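test_that("haplotype tables validate frequencies and reject duplicates", {
  fx <- three_hap_fixture()
  expect_s3_class(fx$table, "haplotype_table")
  expect_error(haplotype_table("A*01:01", "B*01:01", "DRB1*01:01", 0), "> 0")
  expect_error(
    haplotype_table(rep("A*01:01", 2), rep("B*01:01", 2), rep("DRB1*01:01", 2),
                    c(0.5, 0.5)),
    "duplicate")
  path <- withr::local_tempfile(fileext = ".csv")
  write_haplotype_table(fx$table, path)
  expect_equal(as.data.frame(read_haplotype_table(path)), as.data.frame(fx$table))
})

test_that("completion weights follow renormalized Hardy-Weinberg pairing", {
  fx <- three_hap_fixture(f1 = 0.5, f2 = 0.3, f3 = 0.2)
  # typing consistent with exactly one haplotype pair: H1 homozygous
  t_hom <- parse_split_typing(c("A1", "", "B1", "", "DR1", ""), fx$library)
  cs <- enumerate_completions(t_hom, fx$table, fx$library)
  expect_length(cs$genotypes, 1L)
  expect_equal(cs$weights, 1.0)

  # typing consistent with the two heterozygous pairs (H1,H2) and (H1,H3):
  # weights 2*f1*f2 and 2*f1*f3, normalized
  t_het <- parse_split_typing(c("A1", "A2", "B1", "B2", "DR1", "DR2"), fx$library)
  cs2 <- enumerate_completions(t_het, fx$table, fx$library)
  expect_length(cs2$genotypes, 2L)
  expect_equal(sort(cs2$weights), sort(c(0.3, 0.2) / 0.5), tolerance = 1e-12)

  # typing whose antigen maps to no haplotype
  lib_plus <- allele_library(
    locus = c(fx$library$locus, "A"), name = c(fx$library$name, "A*09:01"),
    split = c(fx$library$split, "A9"),
    protein = c(fx$library$protein, strrep("L", 20)))
  t_bad <- parse_split_typing(c("A9", "A1", "B1", "B2", "DR1", "DR2"), lib_plus)
  expect_error(enumerate_completions(t_bad, fx$table, lib_plus),
               "unresolvable")
})

test_that("completion weights sum to one over random resolvable typings", {
  set.seed(515)
  for (rep in 1:8) {
    ref <- tiny_reference(600 + rep)
    for (i in 1:10) {
      # draw a true haplotype pair so the typing is resolvable by construction
      idx <- sample.int(nrow(ref$haplotypes), 2, replace = TRUE,
                        prob = ref$haplotypes$freq)
      g <- genotype(ref$haplotypes$a_allele[idx],
                    ref$haplotypes$b_allele[idx],
                    ref$haplotypes$drb1_allele[idx], ref$library)
      typing <- genotype_to_split(g, ref$library)
      cs <- enumerate_completions(typing, ref$haplotypes, ref$library)
      expect_equal(sum(cs$weights), 1, tolerance = 1e-9)
      # every completion projects back onto the input typing
      for (gg in cs$genotypes) {
        expect_equal(unclass(genotype_to_split(gg, ref$library)), unclass(typing))
      }
    }
  }
})

test_that("imputed mean and SD match hand-computed weighted moments", {
  fx <- three_hap_fixture(f1 = 0.5, f2 = 0.25, f3 = 0.25)
  t_het <- parse_split_typing(c("A1", "A2", "B1", "B2", "DR1", "DR2"), fx$library)
  t_hom <- parse_split_typing(c("A1", "", "B1", "", "DR1", ""), fx$library)
  # recipient resolves uniquely; donor resolves to two equiprobable genotypes.
  # A scorer returning 10 for one donor genotype and 20 for the other gives
  # mean 15, sd 5 (weighted population moments).
  scorer <- function(d, r) if (d$A[2] == "A*02:01") 10 else 20
  sc <- imputed_pair_score(t_het, t_hom, fx$table, fx$library, scorer)
  expect_equal(sc$mean, 15)
  expect_equal(sc$sd, 5)
  expect_equal(sc$n_completions, 2L)

  # both typings single-completion: sd exactly 0
  sc2 <- imputed_pair_score(t_hom, t_hom, fx$table, fx$library,
                            function(d, r) 7)
  expect_equal(sc2$mean, 7)
  expect_equal(sc2$sd, 0)
  expect_equal(sc2$n_completions, 1L)
})

test_that("imputed moments equal exhaustive enumeration on random tables", {
  # independent oracle: loop over all haplotype pairs for donor and recipient,
  # keep those whose split projection matches, weigh by HWE products, and
  # accumulate raw moments of the hash scorer
  oracle <- function(donor_t, recip_t, tab, lib) {
    splits <- function(names) lib$split[match(names, lib$name)]
    side <- function(typing) {
      out <- list()
      for (i in seq_len(nrow(tab))) for (j in i:nrow(tab)) {
        pa <- sort(splits(c(tab$a_allele[i], tab$a_allele[j])))
        pb <- sort(splits(c(tab$b_allele[i], tab$b_allele[j])))
        pd <- sort(splits(c(tab$drb1_allele[i], tab$drb1_allele[j])))
        if (all(pa == typing$A) && all(pb == typing$B) && all(pd == typing$DRB1)) {
          w <- tab$freq[i] * tab$freq[j] * if (i != j) 2 else 1
          g <- genotype(c(tab$a_allele[i], tab$a_allele[j]),
                        c(tab$b_allele[i], tab$b_allele[j]),
                        c(tab$drb1_allele[i], tab$drb1_allele[j]))
          out[[length(out) + 1L]] <- list(g = g, w = w)
        }
      }
      out
    }
    dn <- side(donor_t); rc <- side(recip_t)
    w_tot <- 0; m1 <- 0
    for (a in dn) for (b in rc) {
      w <- a$w * b$w
      w_tot <- w_tot + w
      m1 <- m1 + w * hash_scorer(a$g, b$g)
    }
    m1 <- m1 / w_tot
    v <- 0
    for (a in dn) for (b in rc) {
      v <- v + a$w * b$w / w_tot * (hash_scorer(a$g, b$g) - m1)^2
    }
    list(mean = m1, sd = sqrt(v))
  }
  set.seed(626)
  for (rep in 1:6) {
    ref <- tiny_reference(700 + rep)
    keep <- sample.int(nrow(ref$haplotypes),
                       min(nrow(ref$haplotypes), sample(3:8, 1)))
    tab <- haplotype_table(ref$haplotypes$a_allele[keep],
                           ref$haplotypes$b_allele[keep],
                           ref$haplotypes$drb1_allele[keep],
                           ref$haplotypes$freq[keep])
    draw_typing <- function() {
      idx <- sample(seq_len(nrow(tab)), 2, replace = TRUE)
      genotype_to_split(genotype(tab$a_allele[idx], tab$b_allele[idx],
                                 tab$drb1_allele[idx], ref$library),
                        ref$library)
    }
    for (i in 1:5) {
      dt <- draw_typing(); rt <- draw_typing()
      got <- imputed_pair_score(dt, rt, tab, ref$library, hash_scorer)
      want <- oracle(dt, rt, tab, ref$library)
      expect_equal(got$mean, want$mean, tolerance = 1e-10)
      expect_equal(got$sd, want$sd, tolerance = 1e-10)
    }
  }
})

test_that("score statistics are invariant under allele-synonym splitting", {
  # replacing a haplotype of frequency f by two allele-synonym haplotypes of
  # frequency f/2 each (same splits, identical proteins) leaves the imputed
  # mean and SD unchanged as long as the scorer sees only sequences
  fx <- three_hap_fixture(f1 = 0.4, f2 = 0.4, f3 = 0.2)
  lib <- fx$library
  lib2 <- allele_library(
    locus = c(lib$locus, "A"), name = c(lib$name, "A*01:09"),
    split = c(lib$split, "A1"),
    protein = c(lib$protein, lib$protein[match("A*01:01", lib$name)]))
  tab_split <- haplotype_table(
    a_allele = c("A*01:01", "A*01:09", "A*02:01", "A*02:02"),
    b_allele = c("B*01:01", "B*01:01", "B*02:01", "B*02:02"),
    drb1_allele = c("DRB1*01:01", "DRB1*01:01", "DRB1*02:01", "DRB1*02:02"),
    freq = c(0.2, 0.2, 0.4, 0.2))
  seq_scorer <- function(d, r) {
    prot <- function(g) paste(sort(lib2$protein[match(unlist(g), lib2$name)]),
                              collapse = "")
    (nchar(prot(d)) + sum(utf8ToInt(prot(r)))) %% 53
  }
  t1 <- parse_split_typing(c("A1", "A2", "B1", "B2", "DR1", "DR2"), lib)
  t2 <- parse_split_typing(c("A1", "", "B1", "", "DR1", ""), lib)
  a <- imputed_pair_score(t1, t2, fx$table, lib2, seq_scorer)
  b <- imputed_pair_score(t1, t2, tab_split, lib2, seq_scorer)
  expect_equal(a$mean, b$mean, tolerance = 1e-10)
  expect_equal(a$sd, b$sd, tolerance = 1e-10)
})

test_that("cohort scoring caches typing pairs and flags unresolvable rows", {
  fx <- three_hap_fixture()
  calls <- 0L
  counting_scorer <- function(d, r) {
    calls <<- calls + 1L
    hash_scorer(d, r)
  }
  row_of <- function(d, r) {
    stats::setNames(as.list(c(d, r)),
                    c(paste0("donor_", c("a1","a2","b1","b2","dr1","dr2")),
                      paste0("recipient_", c("a1","a2","b1","b2","dr1","dr2"))))
  }
  hom <- c("A1", "A1", "B1", "B1", "DR1", "DR1")
  coh <- rbind(
    as.data.frame(row_of(hom, hom)),
    as.data.frame(row_of(hom, hom)),           # duplicate typing pair
    as.data.frame(row_of(c("A2", "A2", "B2", "B2", "DR2", "DR2"), hom)))
  out <- score_cohort(coh, fx$table, fx$library, counting_scorer)
  # hom->hom resolves to 1x1 completion pairs; second row is a cache hit.
  # third row: A2/B2/DR2 typing resolves to 3 genotypes (H2/H2, H2/H3, H3/H3)
  expect_equal(calls, 1L + 3L)
  expect_true(all(is.na(out$score_error)))
  expect_equal(out$hla_mm[1], 0L)
  expect_equal(out$hla_mm[3], 3L)  # one unique mismatched antigen per locus
  expect_equal(out$pirche_mean[1], out$pirche_mean[2])

  # unresolvable row is flagged, others scored
  lib_plus <- allele_library(
    locus = c(fx$library$locus, "A"), name = c(fx$library$name, "A*09:01"),
    split = c(fx$library$split, "A9"),
    protein = c(fx$library$protein, strrep("L", 20)))
  coh2 <- rbind(as.data.frame(row_of(hom, hom)),
                as.data.frame(row_of(c("A9", "A9", "B1", "B1", "DR1", "DR1"), hom)))
  out2 <- score_cohort(coh2, fx$table, lib_plus, hash_scorer)
  expect_true(is.na(out2$score_error[1]))
  expect_match(out2$score_error[2], "unresolvable")
  expect_true(is.na(out2$pirche_mean[2]))
  expect_false(is.na(out2$pirche_mean[1]))

  # HLA-identical, uniquely-resolving pairs with a genuine epitope scorer
  # give mean 0 and sd 0
  ref <- tiny_reference(808)
  scorer <- genotype_scorer(ref$library, ref$predictor)
  unique_typing <- NULL
  for (i in seq_len(nrow(ref$haplotypes))) {
    g <- genotype(rep(ref$haplotypes$a_allele[i], 2),
                  rep(ref$haplotypes$b_allele[i], 2),
                  rep(ref$haplotypes$drb1_allele[i], 2), ref$library)
    ty <- genotype_to_split(g, ref$library)
    cs <- enumerate_completions(ty, ref$haplotypes, ref$library)
    if (length(cs$genotypes) == 1L) { unique_typing <- ty; break }
  }
  expect_false(is.null(unique_typing))
  fields <- c(unique_typing$A, unique_typing$B, unique_typing$DRB1)
  coh3 <- as.data.frame(row_of(fields, fields))
  out3 <- score_cohort(coh3, ref$haplotypes, ref$library, scorer)
  expect_equal(out3$pirche_mean, 0)
  expect_equal(out3$hla_mm, 0L)
})
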