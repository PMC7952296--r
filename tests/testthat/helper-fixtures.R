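# Fixtures built in code: a hand-made engineered library whose epitope
# arithmetic can be done on paper, plus random toy instances for property
# and oracle tests.

# Predictor whose PWM rewards tryptophan only: a window's score is the
# number of W residues it contains, the core is the leftmost most-W window,
# and a peptide is presented iff its best window holds >= 1 W. This makes
# presented cores countable by eye.
w_counting_predictor <- function(presenters) {
  w <- matrix(0, nrow = 9, ncol = 20,
              dimnames = list(NULL, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  w[, "W"] <- 1
  pwm_predictor(stats::setNames(
    lapply(presenters, function(x) list(weights = w, threshold = 1)),
    presenters))
}

# Library in which donor A-locus alleles carry engineered W motifs while
# every other protein is a plain poly-A stretch (self everywhere).
engineered_library <- function(a_proteins) {
  blank <- strrep("A", 30)
  n <- length(a_proteins)
  allele_library(
    locus   = c(rep("A", n + 1), "B", "B", "DRB1", "DRB1"),
    name    = c(sprintf("A*%02d:01", seq_len(n)), sprintf("A*%02d:01", n + 1),
                "B*01:01", "B*02:01", "DRB1*01:01", "DRB1*02:01"),
    split   = c(paste0("A", seq_len(n)), paste0("A", n + 1),
                "B1", "B2", "DR1", "DR2"),
    protein = c(a_proteins, blank, blank, blank, blank, blank)
  )
}

# Small random reference data on a reduced alphabet, cheap enough for
# brute-force oracles.
tiny_reference <- function(seed, protein_length = 25L,
                           alphabet = c("A", "C", "D", "E", "F", "G")) {
  cfg <- generator_config(
    n_patients = 1, seed = seed,
    n_splits = c(A = 2L, B = 2L, DRB1 = 2L), alleles_per_split = 2L,
    protein_length = protein_length, alphabet = alphabet,
    split_divergence = 0.25, allele_divergence = 0.10,
    n_haplotypes = 8L, presentation_quantile = 0.6)
  synthesize_reference_data(cfg)
}

random_genotype <- function(library) {
  pick <- function(loc) sample(library$name[library$locus == loc], 2, replace = TRUE)
  genotype(pick("A"), pick("B"), pick("DRB1"), library)
}

random_split_typing <- function(library) {
  pick <- function(loc) sample(unique(library$split[library$locus == loc]),
                               2, replace = TRUE)
  parse_split_typing(c(pick("A"), pick("B"), pick("DRB1")), library)
}

# 3-haplotype table over the engineered library layout used by imputation
# examples: H2 and H3 share all split antigens but differ in alleles.
three_hap_fixture <- function(f1 = 0.5, f2 = 0.3, f3 = 0.2) {
  lib <- allele_library(
    locus   = c("A", "A", "A", "B", "B", "B", "DRB1", "DRB1", "DRB1"),
    name    = c("A*01:01", "A*02:01", "A*02:02",
                "B*01:01", "B*02:01", "B*02:02",
                "DRB1*01:01", "DRB1*02:01", "DRB1*02:02"),
    split   = c("A1", "A2", "A2", "B1", "B2", "B2", "DR1", "DR2", "DR2"),
    protein = strrep(c("A", "C", "D", "E", "F", "G", "H", "I", "K"), 20)
  )
  tab <- haplotype_table(
    a_allele    = c("A*01:01", "A*02:01", "A*02:02"),
    b_allele    = c("B*01:01", "B*02:01", "B*02:02"),
    drb1_allele = c("DRB1*01:01", "DRB1*02:01", "DRB1*02:02"),
    freq        = c(f1, f2, f3)
  )
  list(library = lib, table = tab)
}

# scorer stub satisfying the genotype-pair -> non-negative count contract,
# deterministic and sensitive to every allele name
hash_scorer <- function(donor, recipient) {
  s <- paste(unlist(donor), unlist(recipient), collapse = "")
  sum(utf8ToInt(s)) %% 97
}
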