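# Epitope-load scoring core: donor 15-mer enumeration, self-peptidome
# subtraction, DRB1 presentation filtering, (9-mer core, presenter) dedup.

#' Enumerate all 15-mer peptides of a protein
#'
#' Sliding windows of length 15 at stride 1, the peptide unit scanned for
#' indirect presentation on MHC class II. Duplicate windows are retained here;
#' deduplication happens at scoring time on the (core, presenter) level.
#'
#' @param protein Amino-acid sequence (single string).
#' @return A `data.frame` with columns `sequence` and `start` (0-based offset);
#'   zero rows when the protein is shorter than 15 residues.
#' @export
#' @examples
#' nrow(enumerate_15mers(strrep("A", 20)))  # 6
enumerate_15mers <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  n <- nchar(protein)
  if (n < 15L) {
    return(data.frame(sequence = character(0), start = integer(0)))
  }
  starts <- seq_len(n - 14L)
  data.frame(sequence = substring(protein, starts, starts + 14L),
             start = starts - 1L, stringsAsFactors = FALSE)
}

#' Recipient self-peptidome
#'
#' The set of all 15-mer peptides of the recipient's own HLA proteins at the
#' configured self loci. Donor peptides found in this set cannot be recognized
#' as foreign and are removed before presentation filtering.
#'
#' @param recipient A [genotype()].
#' @param library An [allele_library()].
#' @param self_loci Loci contributing self peptides; this analysis uses
#'   `c("A", "B", "DRB1")` (the loci the scores were computed from), but the
#'   general algorithm admits additional loci such as `"C"` and `"DQB1"` when
#'   the library carries them.
#' @return Character vector of unique 15-mer sequences.
#' @export
self_peptidome <- function(recipient, library, self_loci = c("A", "B", "DRB1")) {
  stopifnot(inherits(recipient, "genotype"))
  alleles <- unique(unlist(recipient[intersect(self_loci, names(recipient))]))
  proteins <- unique(allele_protein(library, alleles))
  unique(unlist(lapply(proteins, function(p) enumerate_15mers(p)$sequence)))
}

#' Position-weight-matrix presentation predictor
#'
#' A deterministic stand-in for a trained MHC class II presentation predictor,
#' satisfying the predictor contract used by [pirche_ii_score()]: for a 15-mer
#' and a recipient DRB1 allele it scores all seven 9-mer windows against that
#' allele's 9x20 position weight matrix, picks the maximal window (leftmost on
#' ties) as the binding core, and calls the peptide presented when the maximal
#' window score reaches the allele's threshold.
#'
#' @param pwms Named list, one entry per DRB1 allele name; each entry a list
#'   with `weights` (numeric 9 x 20 matrix, columns named by the amino-acid
#'   alphabet) and `threshold` (scalar).
#' @return An object of class `pwm_predictor`.
#' @export
pwm_predictor <- function(pwms) {
  stopifnot(is.list(pwms), length(pwms) >= 1L, !is.null(names(pwms)))
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    if (!is.matrix(p$weights) || nrow(p$weights) != 9L ||
        !all(AA_ALPHABET %in% colnames(p$weights))) {
      stop("PWM for ", nm, " must be a 9-row matrix with amino-acid columns")
    }
    if (!is.numeric(p$threshold) || length(p$threshold) != 1L) {
      stop("PWM for ", nm, " must carry a scalar threshold")
    }
  }
  structure(list(pwms = pwms), class = "pwm_predictor")
}

#' @export
print.pwm_predictor <- function(x, ...) {
  cat("<pwm_predictor>", length(x$pwms), "DRB1 matrices:",
      paste(names(x$pwms), collapse = ", "), "\n")
  invisible(x)
}

#' Predict presentation of 15-mer peptides by one DRB1 allele
#'
#' @param predictor A [pwm_predictor()] (or any object with a
#'   `predict_presentation` method honouring the contract).
#' @param peptides Character vector of 15-mers.
#' @param presenter DRB1 allele name.
#' @return A `data.frame` with columns `peptide`, `presented` (logical),
#'   `core` (9-mer, `NA` when not presented), `affinity_score`.
#' @export
predict_presentation <- function(predictor, peptides, presenter) {
  UseMethod("predict_presentation")
}

#' @export
predict_presentation.pwm_predictor <- function(predictor, peptides, presenter) {
  p <- predictor$pwms[[presenter]]
  if (is.null(p)) stop("no PWM for presenter allele ", presenter)
  if (length(peptides) == 0L) {
    return(data.frame(peptide = character(0), presented = logical(0),
                      core = character(0), affinity_score = numeric(0)))
  }
  if (any(nchar(peptides) != 15L)) stop("peptides must be 15-mers")
  aa <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
               nrow = length(peptides), ncol = 15L, byrow = TRUE)
  w <- p$weights[, AA_ALPHABET, drop = FALSE]
  scores <- matrix(0, nrow = length(peptides), ncol = 7L)
  for (win in 1:7) {
    s <- numeric(length(peptides))
    for (pos in 1:9) {
      s <- s + w[pos, match(aa[, win + pos - 1L], AA_ALPHABET)]
    }
    scores[, win] <- s
  }
  best <- max.col(scores, ties.method = "first")  # leftmost maximal window
  best_score <- scores[cbind(seq_along(peptides), best)]
  presented <- best_score >= p$threshold
  core <- ifelse(presented, substring(peptides, best, best + 8L), NA_character_)
  data.frame(peptide = peptides, presented = presented, core = core,
             affinity_score = best_score, stringsAsFactors = FALSE)
}

#' Epitope-load (PIRCHE-II-style) score for a donor/recipient genotype pair
#'
#' Counts the unique donor-derived HLA peptides predicted to drive indirect
#' CD4+ T-cell allorecognition: all 15-mers of the donor's HLA proteins at the
#' input loci that are absent from the recipient's self-peptidome and are
#' predicted to be presented by a recipient HLA-DRB1 protein. Peptides are
#' deduplicated by their 9-mer binding core per presenting DRB1 protein:
#' identical cores arising from different 15-mers count once for a given
#' presenter, while the same core presented by two distinct DRB1 alleles
#' counts once per presenter.
#'
#' @param donor,recipient [genotype()] objects.
#' @param library An [allele_library()] carrying sequences for all donor
#'   alleles and all recipient alleles at the self and presenting loci.
#' @param predictor A presentation predictor, e.g. [pwm_predictor()].
#' @param self_loci Recipient loci contributing the self-peptidome.
#' @param donor_loci Donor loci whose proteins are scanned for peptides.
#' @return An object of class `pirche_result`: list with `raw_score`
#'   (non-negative integer), `pairs` (`data.frame` of counted
#'   `core`/`presenter` pairs) and `per_presenter` (named count per DRB1
#'   allele).
#' @export
#' @examples
#' ref <- synthesize_reference_data(generator_config(seed = 1))
#' don <- genotype(c("A*01:01", "A*02:01"), c("B*01:01", "B*02:01"),
#'                 c("DRB1*01:01", "DRB1*02:01"), ref$library)
#' pirche_ii_score(don, don, ref$library, ref$predictor)$raw_score  # 0
pirche_ii_score <- function(donor, recipient, library, predictor,
                            self_loci = c("A", "B", "DRB1"),
                            donor_loci = c("A", "B", "DRB1")) {
  stopifnot(inherits(donor, "genotype"), inherits(recipient, "genotype"))
  donor_alleles <- unique(unlist(donor[intersect(donor_loci, names(donor))]))
  donor_proteins <- unique(allele_protein(library, donor_alleles))
  donor_peps <- unique(unlist(lapply(donor_proteins,
                                     function(p) enumerate_15mers(p)$sequence)))
  self <- self_peptidome(recipient, library, self_loci)
  foreign <- setdiff(donor_peps, self)
  presenters <- unique(recipient$DRB1)
  allele_protein(library, presenters)  # fail early on missing sequence
  pairs <- list()
  per_presenter <- stats::setNames(integer(length(presenters)), presenters)
  for (pr in presenters) {
    calls <- predict_presentation(predictor, foreign, pr)
    cores <- unique(calls$core[calls$presented])
    per_presenter[pr] <- length(cores)
    if (length(cores)) {
      pairs[[pr]] <- data.frame(core = cores, presenter = pr,
                                stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
           else data.frame(core = character(0), presenter = character(0))
  structure(list(raw_score = nrow(pairs), pairs = pairs,
                 per_presenter = per_presenter),
            class = "pirche_result")
}

#' @export
print.pirche_result <- function(x, ...) {
  cat("<pirche_result> raw score", x$raw_score, "(",
      paste(sprintf("%s: %d", names(x$per_presenter), x$per_presenter),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Naive reference implementation of the epitope-load score
#'
#' Computes the same quantity as [pirche_ii_score()] with plain nested loops
#' and no set machinery or caching; retained as an independent cross-check for
#' the test suite, not for production use.
#'
#' @inheritParams pirche_ii_score
#' @return Integer score.
#' @export
brute_force_score <- function(donor, recipient, library, predictor,
                              self_loci = c("A", "B", "DRB1"),
                              donor_loci = c("A", "B", "DRB1")) {
  self <- character(0)
  for (loc in intersect(self_loci, names(recipient))) {
    for (al in recipient[[loc]]) {
      prot <- allele_protein(library, al)
      if (nchar(prot) >= 15L) {
        for (s in 1:(nchar(prot) - 14L)) {
          self <- c(self, substr(prot, s, s + 14L))
        }
      }
    }
  }
  counted <- character(0)
  for (loc in intersect(donor_loci, names(donor))) {
    for (al in unique(donor[[loc]])) {
      prot <- allele_protein(library, al)
      if (nchar(prot) < 15L) next
      for (s in 1:(nchar(prot) - 14L)) {
        pep <- substr(prot, s, s + 14L)
        if (pep %in% self) next
        for (pr in unique(recipient$DRB1)) {
          call <- predict_presentation(predictor, pep, pr)
          if (call$presented) {
            key <- paste(call$core, pr)
            if (!key %in% counted) counted <- c(counted, key)
          }
        }
      }
    }
  }
  length(counted)
}

#' Build a cached genotype-pair scorer
#'
#' Returns a function `(donor, recipient) -> raw score` wrapping
#' [pirche_ii_score()] with two layers of memoisation: presentation calls per
#' (peptide, presenter) and scores per genotype pair. Scores are deterministic,
#' so caching is safe; the cache persists across calls, which makes batch
#' scoring of cohorts and of imputation completion sets cheap.
#'
#' @inheritParams pirche_ii_score
#' @return A function of `(donor, recipient)` returning a numeric score.
#' @export
genotype_scorer <- function(library, predictor,
                            self_loci = c("A", "B", "DRB1"),
                            donor_loci = c("A", "B", "DRB1")) {
  # integer-coded peptide vocabulary over the whole library, computed once
  pep_lists <- lapply(library$protein, function(p) enumerate_15mers(p)$sequence)
  vocab <- unique(unlist(pep_lists))
  pep_ids <- lapply(pep_lists, match, table = vocab)
  names(pep_ids) <- library$name
  core_maps <- new.env(parent = emptyenv())  # presenter -> core id per vocab entry
  core_ids_for <- function(presenter) {
    m <- core_maps[[presenter]]
    if (is.null(m)) {
      calls <- predict_presentation(predictor, vocab, presenter)
      m <- ifelse(calls$presented, match(calls$core, unique(calls$core)), NA_integer_)
      core_maps[[presenter]] <- m
    }
    m
  }
  score_cache <- new.env(parent = emptyenv())
  ids_of <- function(alleles) {
    idx <- match(alleles, library$name)
    if (anyNA(idx)) {
      stop("allele(s) without sequence in library: ",
           paste(alleles[is.na(idx)], collapse = ", "))
    }
    unique(unlist(pep_ids[idx], use.names = FALSE))
  }
  function(donor, recipient) {
    key <- paste(genotype_key(donor), "->", genotype_key(recipient))
    hit <- score_cache[[key]]
    if (!is.null(hit)) return(hit)
    donor_ids <- ids_of(unique(unlist(donor[intersect(donor_loci, names(donor))])))
    self_ids <- ids_of(unique(unlist(recipient[intersect(self_loci, names(recipient))])))
    foreign <- setdiff(donor_ids, self_ids)
    score <- 0L
    for (pr in unique(recipient$DRB1)) {
      cores <- core_ids_for(pr)[foreign]
      score <- score + length(unique(cores[!is.na(cores)]))
    }
    score_cache[[key]] <- score
    score
  }
}

#' Read / write PWM predictor configuration
#'
#' The predictor configuration is a YAML document with one block per DRB1
#' allele holding the threshold and the 9x20 weight matrix (rows = core
#' positions, columns = the amino-acid alphabet in standard order).
#'
#' @param path File path.
#' @return `read_pwm_config`: a [pwm_predictor()].
#' @export
read_pwm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pwms <- lapply(cfg, function(entry) {
    w <- do.call(rbind, entry$weights)
    colnames(w) <- AA_ALPHABET
    list(weights = w, threshold = entry$threshold)
  })
  pwm_predictor(pwms)
}

#' @rdname read_pwm_config
#' @param predictor A [pwm_predictor()].
#' @export
write_pwm_config <- function(predictor, path) {
  stopifnot(inherits(predictor, "pwm_predictor"))
  cfg <- lapply(predictor$pwms, function(p) {
    list(threshold = p$threshold,
         weights = lapply(seq_len(9), function(i) unname(p$weights[i, AA_ALPHABET])))
  })
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(predictor)
}
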