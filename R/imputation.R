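# Genotype imputation from split typings via A~B~DRB1 haplotype frequencies.

#' Construct / read an A~B~DRB1 haplotype frequency table
#'
#' Population haplotype frequencies (NMDP-style) are the basis for imputing
#' two-field genotypes from split-level typings. Frequencies must be positive
#' but need not sum to one; they are renormalized over the set of haplotype
#' pairs consistent with an observed typing.
#'
#' @param a_allele,b_allele,drb1_allele Character vectors of two-field allele
#'   names.
#' @param freq Positive numeric frequencies.
#' @return An object of class `haplotype_table` (a `data.frame`).
#' @export
haplotype_table <- function(a_allele, b_allele, drb1_allele, freq) {
  df <- data.frame(a_allele = toupper(a_allele), b_allele = toupper(b_allele),
                   drb1_allele = toupper(drb1_allele), freq = as.numeric(freq),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("haplotype table is empty")
  if (any(!is.finite(df$freq) | df$freq <= 0)) stop("haplotype frequencies must be > 0")
  key <- paste(df$a_allele, df$b_allele, df$drb1_allele, sep = "~")
  if (anyDuplicated(key)) {
    stop("duplicate haplotype(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  class(df) <- c("haplotype_table", "data.frame")
  df
}

#' @rdname haplotype_table
#' @param path CSV file with columns `a_allele,b_allele,drb1_allele,freq`.
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("a_allele", "b_allele", "drb1_allele", "freq")
  if (!all(need %in% names(df))) {
    stop("haplotype CSV must have columns ", paste(need, collapse = ","))
  }
  haplotype_table(df$a_allele, df$b_allele, df$drb1_allele, df$freq)
}

#' @rdname haplotype_table
#' @param table A `haplotype_table`.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplotype_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

haplotype_splits <- function(table, library) {
  idx <- function(names) {
    i <- match(names, library$name)
    if (anyNA(i)) {
      stop("haplotype allele(s) missing from library: ",
           paste(unique(names[is.na(i)]), collapse = ", "))
    }
    library$split[i]
  }
  data.frame(a = idx(table$a_allele), b = idx(table$b_allele),
             drb1 = idx(table$drb1_allele), stringsAsFactors = FALSE)
}

#' Enumerate genotype completions of a split typing
#'
#' Finds all unordered pairs of haplotypes whose combined split projection
#' matches the observed typing at every locus, weights each pair by the
#' Hardy-Weinberg pairing probability (`f1 * f2`, doubled for heterozygous
#' pairs), renormalizes over the consistent set, and merges haplotype pairs
#' that collapse to the same two-field genotype.
#'
#' @param typing A `split_typing`.
#' @param table A [haplotype_table()].
#' @param library An [allele_library()] mapping haplotype alleles to splits.
#' @return An object of class `completion_set`: list with `genotypes` (list of
#'   [genotype()]) and `weights` (numeric, summing to 1).
#' @export
enumerate_completions <- function(typing, table, library) {
  stopifnot(inherits(typing, "split_typing"), inherits(table, "haplotype_table"))
  sp <- haplotype_splits(table, library)
  n <- nrow(table)
  # candidate haplotypes: each locus split must appear in the typing's pair
  cand <- which(sp$a %in% typing$A & sp$b %in% typing$B & sp$drb1 %in% typing$DRB1)
  keys <- character(0); weights <- numeric(0); genos <- list()
  for (ii in seq_along(cand)) {
    for (jj in ii:length(cand)) {
      i <- cand[ii]; j <- cand[jj]
      ok <- all(sort(c(sp$a[i], sp$a[j])) == typing$A) &&
            all(sort(c(sp$b[i], sp$b[j])) == typing$B) &&
            all(sort(c(sp$drb1[i], sp$drb1[j])) == typing$DRB1)
      if (!ok) next
      w <- table$freq[i] * table$freq[j] * if (i != j) 2 else 1
      g <- genotype(c(table$a_allele[i], table$a_allele[j]),
                    c(table$b_allele[i], table$b_allele[j]),
                    c(table$drb1_allele[i], table$drb1_allele[j]))
      key <- genotype_key(g)
      at <- match(key, keys)
      if (is.na(at)) {
        keys <- c(keys, key); weights <- c(weights, w)
        genos[[length(genos) + 1L]] <- g
      } else {
        weights[at] <- weights[at] + w
      }
    }
  }
  if (length(genos) == 0L) {
    missing <- HLA_LOCI[vapply(list(typing$A %in% sp$a, typing$B %in% sp$b,
                                    typing$DRB1 %in% sp$drb1),
                               function(x) !all(x), logical(1))]
    stop("unresolvable typing [", format(typing), "]",
         if (length(missing)) paste0(": no haplotype carries the typed split at loci ",
                                     paste(missing, collapse = ", "))
         else ": no consistent haplotype pair in the table")
  }
  structure(list(genotypes = genos, weights = weights / sum(weights)),
            class = "completion_set")
}

#' @export
print.completion_set <- function(x, ...) {
  cat("<completion_set>", length(x$genotypes), "genotype completion(s)\n")
  for (i in seq_along(x$genotypes)) {
    cat(sprintf("  %.4g  %s\n", x$weights[i], format(x$genotypes[[i]])))
  }
  invisible(x)
}

#' Frequency-weighted epitope score of a split-typed donor/recipient pair
#'
#' Enumerates donor and recipient genotype completions independently, forms
#' the product distribution over genotype pairs, scores every pair, and
#' returns the weighted mean score with its weighted (population) standard
#' deviation. The SD reflects the accuracy with which the score can be known
#' from split-level typing: it is 0 when both typings resolve uniquely.
#'
#' @param donor,recipient `split_typing` objects.
#' @param table A [haplotype_table()].
#' @param library An [allele_library()].
#' @param scorer A function `(donor_genotype, recipient_genotype) -> score`,
#'   e.g. from [genotype_scorer()].
#' @return An object of class `imputed_score`: list with `mean`, `sd`,
#'   `n_completions`.
#' @export
imputed_pair_score <- function(donor, recipient, table, library, scorer) {
  dc <- enumerate_completions(donor, table, library)
  rc <- enumerate_completions(recipient, table, library)
  scores <- numeric(0); weights <- numeric(0)
  for (i in seq_along(dc$genotypes)) {
    for (j in seq_along(rc$genotypes)) {
      scores <- c(scores, scorer(dc$genotypes[[i]], rc$genotypes[[j]]))
      weights <- c(weights, dc$weights[i] * rc$weights[j])
    }
  }
  m <- sum(weights * scores)
  v <- sum(weights * (scores - m)^2)
  structure(list(mean = m, sd = sqrt(max(v, 0)),
                 n_completions = length(scores)),
            class = "imputed_score")
}

#' @export
print.imputed_score <- function(x, ...) {
  cat(sprintf("<imputed_score> mean %.3f sd %.3f over %d completion pair(s)\n",
              x$mean, x$sd, x$n_completions))
  invisible(x)
}

#' Score a cohort of split-typed transplants
#'
#' Batch driver: for every row, imputes the donor/recipient epitope score and
#' counts HLA A+B+DRB1 mismatches. Results are cached per unique typing pair.
#' Rows whose typing cannot be resolved against the haplotype table are
#' flagged in `score_error` and left `NA`, never dropped.
#'
#' @param cohort A `data.frame` with donor typing columns
#'   `donor_a1,donor_a2,donor_b1,donor_b2,donor_dr1,donor_dr2` and recipient
#'   columns `recipient_a1,...,recipient_dr2` (blank second field =
#'   homozygous).
#' @param table A [haplotype_table()].
#' @param library An [allele_library()].
#' @param scorer A genotype-pair scorer, e.g. [genotype_scorer()].
#' @return The cohort with columns `pirche_mean`, `pirche_sd`,
#'   `n_completions`, `hla_mm`, `score_error` appended.
#' @export
score_cohort <- function(cohort, table, library, scorer) {
  d_cols <- paste0("donor_", c("a1", "a2", "b1", "b2", "dr1", "dr2"))
  r_cols <- paste0("recipient_", c("a1", "a2", "b1", "b2", "dr1", "dr2"))
  miss <- setdiff(c(d_cols, r_cols), names(cohort))
  if (length(miss)) stop("cohort lacks typing column(s): ", paste(miss, collapse = ", "))
  cache <- new.env(parent = emptyenv())
  n <- nrow(cohort)
  out <- data.frame(pirche_mean = rep(NA_real_, n), pirche_sd = NA_real_,
                    n_completions = NA_integer_, hla_mm = NA_integer_,
                    score_error = NA_character_)
  for (i in seq_len(n)) {
    res <- tryCatch({
      dt <- parse_split_typing(unlist(cohort[i, d_cols]), library)
      rt <- parse_split_typing(unlist(cohort[i, r_cols]), library)
      key <- paste(format(dt), "->", format(rt))
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- list(score = imputed_pair_score(dt, rt, table, library, scorer),
                    mm = count_hla_mismatches(dt, rt)$total)
        cache[[key]] <- hit
      }
      hit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$score_error[i] <- conditionMessage(res)
    } else {
      out$pirche_mean[i] <- res$score$mean
      out$pirche_sd[i] <- res$score$sd
      out$n_completions[i] <- res$score$n_completions
      out$hla_mm[i] <- res$mm
    }
  }
  cbind(cohort, out)
}
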