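#' @keywords internal
"_PACKAGE"

HLA_LOCI <- c("A", "B", "DRB1")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an HLA allele library
#'
#' An allele library holds, for each two-field HLA allele, its locus, its
#' serological split-antigen label and the protein sequence of the exon-2 to
#' exon-5 encoded region. It is the reference object behind epitope scoring,
#' split-typing validation and genotype handling.
#'
#' @param locus Character vector of locus names (`"A"`, `"B"`, `"DRB1"`;
#'   additional self-peptidome loci such as `"C"` or `"DQB1"` are accepted).
#' @param name Character vector of two-field allele names, e.g. `"A*02:01"`.
#'   Case is normalized to upper case; the `*` and `:` separators are required.
#' @param split Character vector of split-antigen labels, e.g. `"A2"`.
#' @param protein Character vector of amino-acid sequences over the standard
#'   20-letter alphabet, already restricted to the exon-2-5 region.
#'
#' @return An object of class `allele_library`: a `data.frame` with columns
#'   `locus`, `name`, `split`, `protein`.
#' @export
#' @examples
#' lib <- allele_library(
#'   locus   = c("A", "A"),
#'   name    = c("A*01:01", "A*02:01"),
#'   split   = c("A1", "A2"),
#'   protein = c("MAVMAPRTLLLLLSG", "MAVMAPRTLVLLLSG")
#' )
allele_library <- function(locus, name, split, protein) {
  name <- toupper(name)
  df <- data.frame(locus = as.character(locus), name = as.character(name),
                   split = as.character(split), protein = toupper(as.character(protein)),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("allele library is empty")
  bad_name <- !grepl("^[A-Z0-9]+\\*[0-9]+:[0-9]+$", df$name)
  if (any(bad_name)) {
    stop("allele names must be two-field ('LOCUS*FF:FF'): ",
         paste(df$name[bad_name], collapse = ", "))
  }
  if (any(df$split == "" | is.na(df$split))) {
    stop("split label missing for allele(s): ",
         paste(df$name[df$split == "" | is.na(df$split)], collapse = ", "))
  }
  key <- paste(df$locus, df$name)
  if (anyDuplicated(key)) {
    stop("duplicate allele(s) in library: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  bad_aa <- vapply(strsplit(df$protein, ""), function(x)
    length(x) == 0L || !all(x %in% AA_ALPHABET), logical(1))
  if (any(bad_aa)) {
    stop("protein sequence empty or containing non-amino-acid characters for: ",
         paste(df$name[bad_aa], collapse = ", "))
  }
  class(df) <- c("allele_library", "data.frame")
  df
}

#' Load an allele library from FASTA and a split-antigen map
#'
#' Reads allele protein sequences from a FASTA file whose headers carry the
#' two-field allele name (`>A*02:01` optionally followed by a description) and
#' joins them with a CSV table mapping every allele to its serological split
#' antigen.
#'
#' @param fasta_path Path to a FASTA file of allele protein sequences.
#' @param split_map_path Path to a CSV file with columns `allele,split`.
#'
#' @return An [allele_library()].
#' @export
load_allele_library <- function(fasta_path, split_map_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  headers <- names(seqs)
  name <- toupper(sub("\\s.*$", "", headers))
  locus <- sub("\\*.*$", "", name)
  map <- utils::read.csv(split_map_path, stringsAsFactors = FALSE)
  if (!all(c("allele", "split") %in% names(map))) {
    stop("split map must have columns 'allele' and 'split'")
  }
  map$allele <- toupper(map$allele)
  idx <- match(name, map$allele)
  if (anyNA(idx)) {
    stop("no split mapping for allele(s): ", paste(name[is.na(idx)], collapse = ", "))
  }
  allele_library(locus = locus, name = name, split = map$split[idx],
                 protein = as.character(seqs))
}

#' Write an allele library to FASTA + split-map CSV
#'
#' Inverse of [load_allele_library()]; used to persist synthetic reference
#' data.
#'
#' @param library An [allele_library()].
#' @param fasta_path,split_map_path Output paths.
#' @return Invisibly, the library.
#' @export
write_allele_library <- function(library, fasta_path, split_map_path) {
  stopifnot(inherits(library, "allele_library"))
  seqs <- Biostrings::AAStringSet(library$protein)
  names(seqs) <- library$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.csv(data.frame(allele = library$name, split = library$split),
                   split_map_path, row.names = FALSE, quote = FALSE)
  invisible(library)
}

valid_splits <- function(library, locus) {
  unique(library$split[library$locus == locus])
}

#' Parse a split-level HLA typing
#'
#' A split typing is one unordered pair of split-antigen labels per locus for
#' HLA-A, -B and -DRB1, the resolution at which deceased-donor allocation
#' typings are reported. A blank second field denotes homozygosity.
#'
#' @param fields Character vector of six fields in the order
#'   `A1, A2, B1, B2, DR1, DR2`.
#' @param library An [allele_library()] used to validate labels.
#'
#' @return An object of class `split_typing`: a named list with elements `A`,
#'   `B`, `DRB1`, each a sorted character pair (homozygous = label repeated).
#' @export
#' @examples
#' lib <- toy_allele_library()
#' parse_split_typing(c("A1", "A2", "B1", "B2", "DR1", "DR2"), lib)
#' parse_split_typing(c("A1", "", "B1", "B2", "DR1", "DR2"), lib)  # A homozygous
parse_split_typing <- function(fields, library) {
  if (length(fields) != 6L) stop("expected six typing fields (A1,A2,B1,B2,DR1,DR2)")
  fields <- as.character(fields)
  fields[is.na(fields)] <- ""
  pairs <- list(A = fields[1:2], B = fields[3:4], DRB1 = fields[5:6])
  out <- lapply(names(pairs), function(loc) {
    p <- pairs[[loc]]
    if (p[1] == "") stop("missing first antigen at locus ", loc)
    if (p[2] == "") p[2] <- p[1]
    known <- valid_splits(library, loc)
    bad <- setdiff(p, known)
    if (length(bad)) {
      stop("unknown split antigen(s) at locus ", loc, ": ", paste(bad, collapse = ", "))
    }
    sort(p)
  })
  names(out) <- names(pairs)
  structure(out, class = "split_typing")
}

split_typing_from_pairs <- function(A, B, DRB1) {
  structure(list(A = sort(A), B = sort(B), DRB1 = sort(DRB1)), class = "split_typing")
}

#' @export
format.split_typing <- function(x, ...) {
  paste(vapply(x, paste, character(1), collapse = "/"), collapse = " ")
}

#' @export
print.split_typing <- function(x, ...) {
  cat("<split_typing>", format(x), "\n")
  invisible(x)
}

#' Count HLA A+B+DRB1 antigen mismatches
#'
#' Counts, at each of the three loci, the unique donor split antigens that are
#' absent from the recipient's antigens at the same locus, and sums them to
#' the familiar 0-6 mismatch scale used by allocation systems. A mismatched
#' antigen of a homozygous donor counts once.
#'
#' @param donor,recipient `split_typing` objects.
#'
#' @return An object of class `mismatch_count`: list with `per_locus`
#'   (named integer, 0-2 each) and `total` (0-6).
#' @export
#' @examples
#' lib <- toy_allele_library()
#' d <- parse_split_typing(c("A2", "", "B1", "B2", "DR1", "DR2"), lib)
#' r <- parse_split_typing(c("A1", "A3", "B1", "B2", "DR1", "DR2"), lib)
#' count_hla_mismatches(d, r)$total  # 1
count_hla_mismatches <- function(donor, recipient) {
  stopifnot(inherits(donor, "split_typing"), inherits(recipient, "split_typing"))
  per <- vapply(HLA_LOCI, function(loc) {
    sum(!unique(donor[[loc]]) %in% recipient[[loc]])
  }, integer(1))
  structure(list(per_locus = per, total = sum(per)), class = "mismatch_count")
}

#' @export
print.mismatch_count <- function(x, ...) {
  cat("<mismatch_count> total", x$total,
      sprintf("(A:%d B:%d DRB1:%d)\n", x$per_locus[["A"]], x$per_locus[["B"]],
              x$per_locus[["DRB1"]]))
  invisible(x)
}

#' Construct a two-field genotype
#'
#' A genotype is one unordered pair of two-field allele names per locus.
#'
#' @param A,B,DRB1 Character pairs of allele names present in `library`.
#' @param library An [allele_library()]; if supplied, allele names are
#'   validated against it.
#' @return An object of class `genotype`.
#' @export
genotype <- function(A, B, DRB1, library = NULL) {
  g <- list(A = sort(toupper(A)), B = sort(toupper(B)), DRB1 = sort(toupper(DRB1)))
  stopifnot(lengths(g) == 2L)
  if (!is.null(library)) {
    missing <- setdiff(unlist(g), library$name)
    if (length(missing)) stop("allele(s) not in library: ", paste(missing, collapse = ", "))
  }
  structure(g, class = "genotype")
}

#' @export
format.genotype <- function(x, ...) {
  paste(vapply(x, paste, character(1), collapse = "/"), collapse = " ")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>", format(x), "\n")
  invisible(x)
}

genotype_key <- function(g) format(g)

#' Project a genotype to its split typing
#'
#' @param g A [genotype()].
#' @param library An [allele_library()].
#' @return A `split_typing`.
#' @export
genotype_to_split <- function(g, library) {
  sp <- function(names) sort(library$split[match(names, library$name)])
  structure(list(A = sp(g$A), B = sp(g$B), DRB1 = sp(g$DRB1)), class = "split_typing")
}

allele_protein <- function(library, names) {
  idx <- match(names, library$name)
  if (anyNA(idx)) {
    stop("allele(s) without sequence in library: ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  library$protein[idx]
}
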