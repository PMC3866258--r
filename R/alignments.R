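# Alignment input, reference degapping and organism-based pairing.
#
# The contact predictor consumes one protein and one RNA multiple sequence
# alignment, each containing the target sequence. Columns where the target
# carries a gap are removed (so alignment length equals target length), and
# rows of the two alignments are paired by organism so that joint column
# frequencies are counted over sequences from the same species.

#' Construct an alignment object
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param alphabet_kind `"protein"` or `"rna"`.
#' @param reference_index Row index of the target sequence (default 1).
#' @param organisms Optional character vector of organism tags; when `NULL`,
#'   tags are extracted from Pfam/Rfam-style identifiers
#'   (`NAME_SPECIES/start-end`: the token between `_` and `/`).
#' @return An `rb_alignment`: list with `ids`, `organisms`, `seq_mat`
#'   (character matrix, rows = sequences), `alphabet_kind`, `reference_index`.
#' @export
alignment <- function(ids, seqs, alphabet_kind = c("protein", "rna"),
                      reference_index = 1L, organisms = NULL) {
  alphabet_kind <- match.arg(alphabet_kind)
  if (length(seqs) == 0L) stop("empty alignment")
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  seqs <- normalize_sequences(seqs, alphabet_kind)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths (", paste(unique(widths), collapse = ", "), ")")
  }
  if (widths[1] == 0L) stop("empty alignment rows")
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(seqs)) {
    stop("reference_index out of range")
  }
  if (is.null(organisms)) organisms <- organism_from_id(ids)
  seq_mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(seq_mat) <- NULL
  structure(
    list(ids = as.character(ids), organisms = as.character(organisms),
         seq_mat = seq_mat, alphabet_kind = alphabet_kind,
         reference_index = reference_index),
    class = "rb_alignment"
  )
}

#' @export
print.rb_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %d sequences x %d columns (reference row %d)\n",
              x$alphabet_kind, nrow(x$seq_mat), ncol(x$seq_mat),
              x$reference_index))
  invisible(x)
}

# Upper-case, map RNA T->U, '.' and any out-of-alphabet character -> gap.
normalize_sequences <- function(seqs, alphabet_kind) {
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (alphabet_kind == "rna") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  alphabet <- if (alphabet_kind == "protein") AA20 else RNA4
  bad <- sprintf("[^%s-]", paste(alphabet, collapse = ""))
  gsub(bad, "-", seqs)
}

# Species token of NAME_SPECIES/start-end style identifiers, else NA.
organism_from_id <- function(ids) {
  m <- regmatches(ids, regexec("^[^_/[:space:]]+_([^/[:space:]]+)", ids))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA (via Biostrings) or Stockholm (Pfam/Rfam dialect;
#' `#=GS <seq> OS <organism>` annotations are honoured when present).
#' Characters are upper-cased, `T` is mapped to `U` for RNA, and any
#' character outside the alphabet (`X`, `B`, ...) becomes a gap so that
#' real Pfam/Rfam files parse.
#'
#' @param path File path.
#' @param format `"fasta"` or `"stockholm"`.
#' @param alphabet_kind `"protein"` or `"rna"`.
#' @param reference_id Optional identifier of the target sequence; when
#'   absent the first row is taken as the target.
#' @return An `rb_alignment` (not yet degapped).
#' @seealso [degap_to_reference()], [pair_by_organism()]
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           alphabet_kind = c("protein", "rna"),
                           reference_id = NULL) {
  format <- match.arg(format)
  alphabet_kind <- match.arg(alphabet_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    ids <- sub("[[:space:]].*$", "", names(set))
    list(ids = ids, seqs = as.character(set), organisms = NULL)
  } else {
    parse_stockholm(path)
  }
  ref <- 1L
  if (!is.null(reference_id)) {
    ref <- match(reference_id, parsed$ids)
    if (is.na(ref)) stop("reference_id not found in alignment: ", reference_id)
  }
  alignment(parsed$ids, parsed$seqs, alphabet_kind,
            reference_index = ref, organisms = parsed$organisms)
}

# Minimal Stockholm reader for the Pfam/Rfam full-alignment dialect:
# sequence lines "name  aligned-seq" (possibly wrapped over blocks),
# "#=GS name OS organism" annotations, "//" terminator.
parse_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- character(0)
  os <- character(0)
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#=GS[[:space:]]", ln)) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) >= 4L && f[3] == "OS") {
        os[f[2]] <- paste(f[-(1:3)], collapse = " ")
      }
      next
    }
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) != 2L) next
    seqs[f[1]] <- paste0(if (f[1] %in% names(seqs)) seqs[f[1]] else "", f[2])
  }
  if (length(seqs) == 0L) stop("no sequences found in Stockholm file: ", path)
  ids <- names(seqs)
  organisms <- organism_from_id(ids)
  if (length(os)) {
    hit <- !is.na(match(ids, names(os)))
    organisms[hit] <- os[ids[hit]]
  }
  list(ids = ids, seqs = unname(seqs), organisms = organisms)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `rb_alignment`.
#' @param path Output file path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "rb_alignment"))
  seqs <- apply(aln$seq_mat, 1L, paste0, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove alignment columns gapped in the target sequence
#'
#' Deletes every column where the reference (target) row carries a gap, so
#' that the alignment length equals the ungapped target length and position
#' indices refer directly to target residues/bases. Idempotent.
#'
#' @param aln An `rb_alignment`.
#' @return The degapped `rb_alignment`.
#' @export
degap_to_reference <- function(aln) {
  stopifnot(inherits(aln, "rb_alignment"))
  ref <- aln$seq_mat[aln$reference_index, ]
  keep <- ref != GAP
  if (!any(keep)) stop("reference row is all gaps")
  aln$seq_mat <- aln$seq_mat[, keep, drop = FALSE]
  aln
}

#' Pair protein and RNA alignment rows by organism
#'
#' Joint column frequencies must be counted over sequences from the same
#' species, so each protein row is matched to the RNA row sharing its
#' organism tag. Organisms present on only one side are dropped; when an
#' organism occurs several times on a side, the first occurrence is used.
#' The two reference rows are always paired with each other.
#'
#' @param protein,rna Degapped `rb_alignment` objects with organism tags.
#' @return An `rb_paired` object: `protein`, `rna` and `pairs`, an
#'   integer matrix with columns `protein_row` and `rna_row`.
#' @export
pair_by_organism <- function(protein, rna) {
  stopifnot(inherits(protein, "rb_alignment"), inherits(rna, "rb_alignment"))
  p_org <- protein$organisms
  r_org <- rna$organisms
  pr <- protein$reference_index
  rr <- rna$reference_index
  used_p <- pr
  used_r <- rr
  pairs <- matrix(c(pr, rr), ncol = 2L)
  common <- intersect(unique(p_org[!is.na(p_org)]), unique(r_org[!is.na(r_org)]))
  if (length(common) == 0L) {
    stop("no organisms in common between the two alignments")
  }
  for (org in common) {
    pi <- which(p_org == org)[1]
    ri <- which(r_org == org)[1]
    if (pi %in% used_p || ri %in% used_r) next
    pairs <- rbind(pairs, c(pi, ri))
    used_p <- c(used_p, pi)
    used_r <- c(used_r, ri)
  }
  colnames(pairs) <- c("protein_row", "rna_row")
  structure(list(protein = protein, rna = rna, pairs = pairs),
            class = "rb_paired")
}

#' @export
print.rb_paired <- function(x, ...) {
  cat(sprintf("paired alignments: %d organism pairs, %d protein x %d RNA positions\n",
              nrow(x$pairs), ncol(x$protein$seq_mat), ncol(x$rna$seq_mat)))
  invisible(x)
}
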