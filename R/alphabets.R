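# Alphabet constants shared across modules. Gap is a first-class symbol for
# coevolution counting, but never occurs in degapped target sequences.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
RNA4 <- c("A", "C", "G", "U")
GAP <- "-"

#' Reduced amino-acid alphabets (Murphy groupings)
#'
#' Returns a grouping scheme mapping the 20 standard amino acids onto
#' 2, 4, 8, 10 or 15 classes (Murphy et al.), or the identity partition
#' for `groups = 20`. The same scheme is used both for counting grouped
#' symbol frequencies in mutual information and for the identity-label
#' features of the contact CRF. For frequency counting the gap character
#' forms its own extra class with index `group_count` (0-based).
#'
#' @param groups Number of amino-acid classes: one of 2, 4, 8, 10, 15, 20.
#' @return An object of class `rb_grouping` with elements `name`,
#'   `group_count` and `mapping` (named integer vector, 0-based group index
#'   per amino acid).
#' @examples
#' g8 <- grouping_scheme(8)
#' g8$mapping[c("M", "L", "G", "A")]  # MLVIC and GA classes
#' @export
grouping_scheme <- function(groups = 20) {
  groups <- as.integer(groups)
  partitions <- list(
    `2`  = "MLVICGATSPFYW/DENQRKH",
    `4`  = "MLVIC/GATSP/FYW/DENQRKH",
    `8`  = "MLVIC/GA/TS/P/FYW/DENQ/RK/H",
    `10` = "MLVI/C/G/A/TS/P/FYW/DENQ/RK/H",
    `15` = "MLVI/C/G/A/T/S/P/FY/W/D/E/N/Q/RK/H",
    `20` = paste(AA20, collapse = "/")
  )
  key <- as.character(groups)
  if (!key %in% names(partitions)) {
    stop("'groups' must be one of 2, 4, 8, 10, 15, 20")
  }
  new_grouping(key, strsplit(partitions[[key]], "/", fixed = TRUE)[[1]])
}

# Build a grouping from an explicit list of class strings (e.g. "MLVIC").
# Used by grouping_scheme() and by tests exercising degenerate partitions.
new_grouping <- function(name, class_strings) {
  mapping <- integer(0)
  for (k in seq_along(class_strings)) {
    aas <- strsplit(class_strings[[k]], "", fixed = TRUE)[[1]]
    mapping[aas] <- k - 1L
  }
  if (!setequal(names(mapping), AA20)) {
    stop("grouping must cover exactly the 20 standard amino acids")
  }
  mapping <- mapping[AA20]
  structure(
    list(name = name, group_count = length(class_strings),
         classes = as.character(class_strings), mapping = mapping),
    class = "rb_grouping"
  )
}

#' @export
print.rb_grouping <- function(x, ...) {
  cat("Amino-acid grouping:", x$name, "classes =", x$group_count, "\n")
  cat(paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

# 0-based grouped index of protein characters; gap -> group_count.
protein_group_index <- function(chars, grouping) {
  idx <- grouping$mapping[chars]
  idx[chars == GAP] <- grouping$group_count
  if (anyNA(idx)) stop("unknown protein character(s): ",
                       paste(unique(chars[is.na(idx)]), collapse = " "))
  unname(idx)
}

# 0-based RNA base index; gap -> 4.
rna_base_index <- function(chars) {
  idx <- match(chars, RNA4) - 1L
  idx[chars == GAP] <- 4L
  if (anyNA(idx)) stop("unknown RNA character(s): ",
                       paste(unique(chars[is.na(idx)]), collapse = " "))
  unname(idx)
}
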