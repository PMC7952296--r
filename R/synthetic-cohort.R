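# Synthetic transplant cohorts with known ground truth: toy allele
# sequences/splits/haplotypes, HWE genotype draws, true epitope scores and
# mismatch counts, confounders with explicit unknown levels, and
# proportional-hazards graft-loss times with death treated as censoring.

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: the toy HLA reference data
#' (split/allele structure, sequence divergence, haplotype pool), the
#' presentation predictor, the true per-unit log-hazards of the two
#' compatibility exposures, confounder effects, and the censoring scheme.
#' Defaults encode the study conditions the analysis stage assumes; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_patients Number of transplants to simulate.
#' @param seed Integer seed; mandatory, drives reference data and cohort.
#' @param n_splits Named integer vector: split antigens per locus.
#' @param alleles_per_split Two-field alleles per split antigen.
#' @param protein_length Length of the toy exon-2-5 protein region.
#' @param alphabet Amino-acid alphabet for toy sequences; the full 20-letter
#'   alphabet by default, reducible (e.g. 6 letters) to make brute-force
#'   oracles cheap.
#' @param split_divergence Per-position substitution probability between a
#'   locus ancestor and each split ancestor; controls how different split
#'   antigens are, hence the epitope-score scale.
#' @param allele_divergence Per-position substitution probability between a
#'   split ancestor and each allele.
#' @param n_haplotypes Size of the A~B~DRB1 haplotype pool.
#' @param dirichlet_concentration Concentration of the Dirichlet draw for
#'   haplotype frequencies (1 = uniform simplex).
#' @param presentation_quantile Quantile of the background window-score
#'   distribution used as each DRB1 PWM's presentation threshold (0.75 keeps
#'   roughly a quarter of windows).
#' @param beta_pirche,beta_hla True log-hazard per adjusted-score unit and per
#'   antigen mismatch; defaults `log(1.102)` and `log(1.095)`.
#' @param interaction If `TRUE`, the epitope effect applies only above
#'   `interaction_threshold` mismatches.
#' @param interaction_threshold Mismatch count above which the epitope effect
#'   acts when `interaction = TRUE`.
#' @param confounder_effects Named list of log-hazard effects; see
#'   `default_confounder_effects()` in the package source for the layout.
#' @param confound_donor_age If `TRUE`, donor age is shifted upward with the
#'   mismatch count, giving a genuinely confounded cohort for sensitivity
#'   tests; exposures and confounders are independent by default.
#' @param event_target Target graft-loss fraction within the follow-up
#'   horizon; the baseline hazard is calibrated to hit it in expectation.
#' @param baseline_hazard Baseline hazard scale per month; overrides the
#'   `event_target` calibration when supplied.
#' @param baseline_shape Weibull shape of the baseline hazard; 1 (the
#'   default) is the exponential baseline, values away from 1 give rising or
#'   falling hazards while preserving proportional hazards.
#' @param censoring_rate Exponential rate of independent censoring (death
#'   with function, loss to follow-up) per month.
#' @param followup_horizon Administrative end of follow-up, months.
#' @param unknown_rate Fraction of subjects whose PRA, dialysis and initial
#'   immunosuppression records are set to `"unknown"`.
#' @param pra_positive Fraction of presensitized (PRA > 0) recipients among
#'   those with a known PRA.
#' @param n_countries Number of reporting countries (Cox strata); baseline
#'   hazards differ by country.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 5000,
                             seed,
                             n_splits = c(A = 4L, B = 4L, DRB1 = 3L),
                             alleles_per_split = 2L,
                             protein_length = 90L,
                             alphabet = AA_ALPHABET,
                             split_divergence = 0.15,
                             allele_divergence = 0.03,
                             n_haplotypes = 20L,
                             dirichlet_concentration = 1,
                             presentation_quantile = 0.75,
                             beta_pirche = log(1.102),
                             beta_hla = log(1.095),
                             interaction = FALSE,
                             interaction_threshold = 3L,
                             confounder_effects = default_confounder_effects(),
                             confound_donor_age = FALSE,
                             event_target = 0.15,
                             baseline_hazard = NULL,
                             baseline_shape = 1,
                             censoring_rate = 1 / 240,
                             followup_horizon = 120,
                             unknown_rate = 0.08,
                             pra_positive = 0.13,
                             n_countries = 6L) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_patients >= 1, protein_length >= 15, baseline_shape > 0,
            all(n_splits >= 1), alleles_per_split >= 1, n_haplotypes >= 1,
            split_divergence >= 0, allele_divergence >= 0,
            presentation_quantile > 0, presentation_quantile < 1,
            censoring_rate >= 0, followup_horizon > 0,
            unknown_rate >= 0, unknown_rate < 1,
            pra_positive >= 0, pra_positive <= 1, n_countries >= 1)
  if (!setequal(names(n_splits), HLA_LOCI)) {
    stop("n_splits must be named A, B, DRB1")
  }
  structure(as.list(environment()), class = "generator_config")
}

default_confounder_effects <- function() {
  list(
    recipient_age = 0.010,  # per year, centered at 50
    donor_age = 0.015,      # per year, centered at 47
    recipient_sex = c(male = 0, female = -0.05),
    donor_sex = c(male = 0, female = 0.05),
    dialysis = c(none = 0, "1-24" = 0.10, "25-60" = 0.20, ">60" = 0.30,
                 unknown = 0.15),
    disease = c(glomerulonephritis = 0, diabetes = 0.30, polycystic = -0.10,
                other = 0.10),
    pra = c("0" = 0, ">0" = 0.25, unknown = 0.10),
    marginal_donor = c(no = 0, yes = 0.30),
    induction = c("none" = 0, "IL-2RA" = -0.05, ATG = 0.10, other = 0.05),
    immunosuppression = c("Tac+MPA" = 0, "CsA+MPA" = 0.15, other = 0.20,
                          unknown = 0.10),
    tx_period = c("1990-1996" = 0.30, "1997-2003" = 0.20, "2004-2010" = 0.10,
                  "2011-2016" = 0),
    cit_hours = 0.010       # per hour, centered at 17
  )
}

mutate_sequence <- function(seq_chars, rate, alphabet) {
  hit <- which(stats::runif(length(seq_chars)) < rate)
  for (i in hit) {
    seq_chars[i] <- sample(setdiff(alphabet, seq_chars[i]), 1L)
  }
  seq_chars
}

#' Synthesize toy HLA reference data
#'
#' Builds an allele library, split map, haplotype frequency table and PWM
#' presentation predictor with the structure the pipeline expects. Per locus
#' an ancestral protein is drawn; split-antigen ancestors diverge from it by
#' point substitutions at `split_divergence`, and alleles within a split
#' diverge from their split ancestor at `allele_divergence`, so alleles of
#' the same split are more alike than alleles of different splits — mirroring
#' serology. Haplotypes are random A~B~DRB1 allele triples with Dirichlet
#' frequencies; each DRB1 allele gets a random 9x20 PWM whose threshold is
#' the configured quantile of its window scores over the whole library
#' peptidome.
#'
#' @param config A [generator_config()].
#' @return List with `library` ([allele_library()]), `haplotypes`
#'   ([haplotype_table()]), `predictor` ([pwm_predictor()]) and `config`.
#' @export
synthesize_reference_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  ab <- config$alphabet
  loci <- HLA_LOCI
  recs <- list()
  for (loc in loci) {
    ancestor <- sample(ab, config$protein_length, replace = TRUE)
    prefix <- if (loc == "DRB1") "DR" else loc
    for (s in seq_len(config$n_splits[[loc]])) {
      split_anc <- mutate_sequence(ancestor, config$split_divergence, ab)
      for (a in seq_len(config$alleles_per_split)) {
        prot <- mutate_sequence(split_anc, config$allele_divergence, ab)
        recs[[length(recs) + 1L]] <- data.frame(
          locus = loc,
          name = sprintf("%s*%02d:%02d", loc, s, a),
          split = paste0(prefix, s),
          protein = paste(prot, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  recs <- do.call(rbind, recs)
  library <- allele_library(recs$locus, recs$name, recs$split, recs$protein)
  pick <- function(loc) {
    pool <- library$name[library$locus == loc]
    sample(pool, config$n_haplotypes, replace = TRUE)
  }
  triples <- unique(data.frame(a = pick("A"), b = pick("B"), d = pick("DRB1"),
                               stringsAsFactors = FALSE))
  freq <- stats::rgamma(nrow(triples), shape = config$dirichlet_concentration)
  freq <- freq / sum(freq)
  haplotypes <- haplotype_table(triples$a, triples$b, triples$d, freq)
  # background window scores over the whole library peptidome set thresholds
  all_peps <- unique(unlist(lapply(library$protein,
                                   function(p) enumerate_15mers(p)$sequence)))
  drb1 <- library$name[library$locus == "DRB1"]
  pwms <- list()
  for (al in drb1) {
    w <- matrix(stats::rnorm(9 * length(ab)), nrow = 9,
                dimnames = list(NULL, ab))
    full <- matrix(0, nrow = 9, ncol = length(AA_ALPHABET),
                   dimnames = list(NULL, AA_ALPHABET))
    full[, ab] <- w
    tmp <- pwm_predictor(stats::setNames(list(list(weights = full, threshold = -Inf)), al))
    scores <- predict_presentation(tmp, all_peps, al)$affinity_score
    pwms[[al]] <- list(weights = full,
                       threshold = stats::quantile(scores,
                                                   config$presentation_quantile,
                                                   names = FALSE))
  }
  list(library = library, haplotypes = haplotypes,
       predictor = pwm_predictor(pwms), config = config)
}

sample_factor <- function(n, levels, probs) {
  factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
}

apply_unknown <- function(f, rate) {
  v <- as.character(f)
  v[stats::runif(length(v)) < rate] <- "unknown"
  factor(v, levels = unique(c(setdiff(levels(f), "unknown"), "unknown")))
}

factor_effect <- function(f, eff) {
  unname(eff[as.character(f)])
}

# expected event fraction under Weibull(shape) PH event times, exponential
# censoring and an administrative cutoff; closed form when shape = 1,
# trapezoidal quadrature otherwise
expected_event_fraction <- function(lambda, cens, horizon, shape = 1) {
  if (shape == 1) {
    tot <- lambda + cens
    return(mean(lambda / tot * (1 - exp(-tot * horizon))))
  }
  # trapezoid on a log-spaced grid (dense near 0, where shape < 1 puts an
  # integrable spike); the [0, t_1] head is handled analytically with S_C ~ 1
  grid <- exp(seq(log(horizon * 1e-6), log(horizon), length.out = 400L))
  g <- vapply(grid, function(t) {
    mean(shape * lambda * t^(shape - 1) * exp(-lambda * t^shape - cens * t))
  }, numeric(1))
  head_mass <- mean(1 - exp(-lambda * grid[1]^shape))
  head_mass + sum(diff(grid) * (g[-1] + g[-length(g)]) / 2)
}

#' Simulate a synthetic transplant cohort
#'
#' Draws donor and recipient genotypes as Hardy-Weinberg haplotype pairs from
#' the reference pool, degrades them to split typings, computes the true
#' (genotype-level, unimputed) epitope score and the antigen mismatch count,
#' adjusts scores onto the 0-6 scale over this cohort, draws confounders
#' independently of the exposures (unless `confound_donor_age`), and draws
#' death-censored graft-loss times from an exponential proportional-hazards
#' model whose linear predictor is
#' `beta_pirche * pirche_adj + beta_hla * hla_mm + confounder effects`, with
#' country-specific baseline hazards, independent exponential censoring and
#' administrative censoring at the follow-up horizon. Because true scores are
#' computed from true genotypes while split typings are also emitted, the
#' imputation stage's error can be studied against ground truth.
#'
#' @param config A [generator_config()].
#' @param reference Reference data from [synthesize_reference_data()];
#'   regenerated from `config` when omitted.
#' @param cohort_seed Seed for the cohort draw (reference data uses
#'   `config$seed`); defaults to `config$seed + 1`. Vary it to obtain
#'   replicate cohorts over a fixed reference.
#' @param scorer Optional pre-built [genotype_scorer()] (pass one to share its
#'   cache across replicate cohorts).
#' @return A `data.frame` of class `synthetic_cohort`, one row per
#'   transplant, with typing columns (`donor_a1` ... `recipient_dr2`),
#'   `hla_mm`, `pirche_raw`, `pirche_adj`, the confounders, `country`,
#'   `time` (months), `event`, and ground-truth columns `truth_donor_genotype`
#'   / `truth_recipient_genotype`. Attribute `"truth"` records the true betas,
#'   the adjustment context, and the calibrated baseline hazard.
#' @export
simulate_cohort <- function(config, reference = synthesize_reference_data(config),
                            cohort_seed = config$seed + 1L, scorer = NULL) {
  stopifnot(inherits(config, "generator_config"))
  library <- reference$library
  haps <- reference$haplotypes
  if (is.null(scorer)) scorer <- genotype_scorer(library, reference$predictor)
  set.seed(cohort_seed)
  n <- config$n_patients
  nh <- nrow(haps)
  draw_pair <- function() {
    h1 <- sample.int(nh, n, replace = TRUE, prob = haps$freq)
    h2 <- sample.int(nh, n, replace = TRUE, prob = haps$freq)
    cbind(pmin(h1, h2), pmax(h1, h2))
  }
  don <- draw_pair()
  rec <- draw_pair()
  # genotypes exist per unique haplotype pair; score per unique pair-of-pairs
  pair_key <- function(m) paste(m[, 1], m[, 2], sep = "_")
  geno_of <- function(i, j) {
    genotype(c(haps$a_allele[i], haps$a_allele[j]),
             c(haps$b_allele[i], haps$b_allele[j]),
             c(haps$drb1_allele[i], haps$drb1_allele[j]))
  }
  all_keys <- unique(c(pair_key(don), pair_key(rec)))
  genos <- lapply(strsplit(all_keys, "_"), function(k)
    geno_of(as.integer(k[1]), as.integer(k[2])))
  names(genos) <- all_keys
  splits <- lapply(genos, genotype_to_split, library = library)
  don_g <- match(pair_key(don), all_keys)
  rec_g <- match(pair_key(rec), all_keys)
  combo <- paste(don_g, rec_g)
  u <- !duplicated(combo)
  mm_u <- mapply(function(i, j) count_hla_mismatches(splits[[i]], splits[[j]])$total,
                 don_g[u], rec_g[u])
  raw_u <- mapply(function(i, j) scorer(genos[[i]], genos[[j]]),
                  don_g[u], rec_g[u])
  at <- match(combo, combo[u])
  hla_mm <- as.integer(mm_u[at])
  pirche_raw <- as.numeric(raw_u[at])
  if (all(pirche_raw == 0)) {
    # divergence 0 (or an over-harsh threshold) collapses every score to 0;
    # the 0-6 adjustment is undefined there, so keep adj at 0 and flag it
    ctx <- NULL
    pirche_adj <- rep(0, n)
  } else {
    ctx <- fit_adjustment(pirche_raw)
    pirche_adj <- as.numeric(adjust_scores(pirche_raw, ctx))
  }
  eff <- config$confounder_effects
  recipient_age <- pmin(pmax(stats::rnorm(n, 49, 15), 18), 78)
  donor_age <- pmin(pmax(stats::rnorm(n, 47, 17), 10), 80)
  if (config$confound_donor_age) {
    donor_age <- pmin(pmax(donor_age + 2.5 * (hla_mm - mean(hla_mm)), 10), 80)
  }
  recipient_sex <- sample_factor(n, c("male", "female"), c(0.62, 0.38))
  donor_sex <- sample_factor(n, c("male", "female"), c(0.57, 0.43))
  dialysis <- apply_unknown(
    sample_factor(n, c("none", "1-24", "25-60", ">60"), c(0.02, 0.30, 0.42, 0.26)),
    config$unknown_rate)
  disease <- sample_factor(n, names(eff$disease), c(0.30, 0.20, 0.15, 0.35))
  pra <- apply_unknown(
    sample_factor(n, c("0", ">0"), c(1 - config$pra_positive, config$pra_positive)),
    config$unknown_rate)
  marginal_donor <- sample_factor(n, c("no", "yes"), c(0.80, 0.20))
  induction <- sample_factor(n, names(eff$induction), c(0.55, 0.25, 0.10, 0.10))
  immunosuppression <- apply_unknown(
    sample_factor(n, c("Tac+MPA", "CsA+MPA", "other"), c(0.33, 0.23, 0.44)),
    config$unknown_rate)
  tx_period <- sample_factor(n, names(eff$tx_period), c(0.14, 0.29, 0.30, 0.27))
  cit_hours <- pmin(pmax(stats::rnorm(n, 17, 7), 2), 48)
  country <- sample_factor(n, paste0("C", seq_len(config$n_countries)),
                           rep(1, config$n_countries))
  country_lh <- stats::setNames(stats::rnorm(config$n_countries, 0, 0.3),
                                levels(country))
  exposure_lp <- config$beta_hla * hla_mm +
    config$beta_pirche * pirche_adj *
      (if (config$interaction) as.numeric(hla_mm > config$interaction_threshold) else 1)
  conf_lp <- eff$recipient_age * (recipient_age - 50) +
    eff$donor_age * (donor_age - 47) +
    factor_effect(recipient_sex, eff$recipient_sex) +
    factor_effect(donor_sex, eff$donor_sex) +
    factor_effect(dialysis, eff$dialysis) +
    factor_effect(disease, eff$disease) +
    factor_effect(pra, eff$pra) +
    factor_effect(marginal_donor, eff$marginal_donor) +
    factor_effect(induction, eff$induction) +
    factor_effect(immunosuppression, eff$immunosuppression) +
    factor_effect(tx_period, eff$tx_period) +
    eff$cit_hours * (cit_hours - 17)
  lp <- exposure_lp + conf_lp + country_lh[as.character(country)]
  shape <- if (is.null(config$baseline_shape)) 1 else config$baseline_shape
  if (is.null(config$baseline_hazard)) {
    lam0 <- stats::uniroot(function(l0)
      expected_event_fraction(l0 * exp(lp), config$censoring_rate,
                              config$followup_horizon, shape) - config$event_target,
      interval = c(1e-12, 100), tol = 1e-12)$root
  } else {
    lam0 <- config$baseline_hazard
  }
  lambda <- lam0 * exp(lp)
  # inverse-transform Weibull PH draw; shape 1 reduces to the exponential
  t_event <- (stats::rexp(n, rate = 1) / lambda)^(1 / shape)
  t_cens <- if (config$censoring_rate > 0) stats::rexp(n, rate = config$censoring_rate)
            else rep(Inf, n)
  time <- pmin(t_event, t_cens, config$followup_horizon)
  event <- as.integer(t_event <= pmin(t_cens, config$followup_horizon))
  typing_cols <- function(idx) {
    sp <- splits[idx]
    data.frame(a1 = vapply(sp, function(s) s$A[1], character(1)),
               a2 = vapply(sp, function(s) s$A[2], character(1)),
               b1 = vapply(sp, function(s) s$B[1], character(1)),
               b2 = vapply(sp, function(s) s$B[2], character(1)),
               dr1 = vapply(sp, function(s) s$DRB1[1], character(1)),
               dr2 = vapply(sp, function(s) s$DRB1[2], character(1)),
               stringsAsFactors = FALSE)
  }
  dt <- typing_cols(don_g); names(dt) <- paste0("donor_", names(dt))
  rt <- typing_cols(rec_g); names(rt) <- paste0("recipient_", names(rt))
  out <- cbind(
    data.frame(id = seq_len(n)), dt, rt,
    data.frame(hla_mm = hla_mm, pirche_raw = pirche_raw, pirche_adj = pirche_adj,
               recipient_age = recipient_age, donor_age = donor_age,
               recipient_sex = recipient_sex, donor_sex = donor_sex,
               dialysis = dialysis, disease = disease, pra = pra,
               marginal_donor = marginal_donor, induction = induction,
               immunosuppression = immunosuppression, tx_period = tx_period,
               cit_hours = cit_hours, country = country,
               time = time, event = event,
               truth_donor_genotype = vapply(genos[don_g], genotype_key, character(1)),
               truth_recipient_genotype = vapply(genos[rec_g], genotype_key, character(1)),
               stringsAsFactors = FALSE))
  attr(out, "truth") <- list(beta_pirche = config$beta_pirche,
                             beta_hla = config$beta_hla,
                             interaction = config$interaction,
                             interaction_threshold = config$interaction_threshold,
                             adjustment = ctx,
                             baseline_hazard = lam0,
                             country_log_hazard = country_lh,
                             event_target = config$event_target)
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Write a synthetic study to disk
#'
#' Persists the cohort CSV, the reference FASTA/split-map/haplotype CSVs, the
#' PWM configuration and a ground-truth sidecar (YAML) into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param reference The matching reference data.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic_study <- function(cohort, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  write_allele_library(reference$library, file.path(dir, "alleles.fasta"),
                       file.path(dir, "split_map.csv"))
  write_haplotype_table(reference$haplotypes, file.path(dir, "haplotypes.csv"))
  write_pwm_config(reference$predictor, file.path(dir, "pwm.yaml"))
  truth <- attr(cohort, "truth")
  yaml::write_yaml(list(beta_pirche = truth$beta_pirche,
                        beta_hla = truth$beta_hla,
                        baseline_hazard = truth$baseline_hazard,
                        cohort_max_log = truth$adjustment$cohort_max_log),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' A tiny fixed allele library for examples
#'
#' A deterministic miniature library (three A splits, two B and two DRB1
#' splits, two alleles each, 30-residue proteins) used across documentation
#' examples and quick experiments.
#'
#' @return An [allele_library()].
#' @export
toy_allele_library <- function() {
  cfg <- generator_config(n_patients = 1, seed = 20260930,
                          n_splits = c(A = 3L, B = 2L, DRB1 = 2L),
                          protein_length = 30L)
  synthesize_reference_data(cfg)$library
}
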