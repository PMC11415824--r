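#' Mobile element template library
#'
#' A `MELibrary` holds the consensus sequences of the mobile element (ME)
#' classes the caller can assign: Alu (~300 bp SINE), L1 (LINE-1, frequently
#' 5'-truncated) and SVA (composite SINE-VNTR-Alu). Consensus sequences of
#' candidate insertions/deletions are aligned against these templates during
#' classification.
#'
#' @name MELibrary
#' @keywords internal
NULL

ME_CLASSES <- c("Alu", "L1", "SVA")

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive). `N` maps to `N`.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("revcomp(): sequence contains non-DNA characters")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Header -> class rule: case-insensitive prefix match. "L1" also accepts
# the spelled-out "LINE1"/"LINE-1" prefix.
.class_from_header <- function(name, class_map = NULL) {
  if (!is.null(class_map) && name %in% names(class_map)) {
    cls <- class_map[[name]]
    if (!cls %in% ME_CLASSES) {
      stop("class_map assigns unknown class '", cls, "' to template '", name, "'")
    }
    return(cls)
  }
  up <- toupper(name)
  if (startsWith(up, "ALU")) return("Alu")
  if (startsWith(up, "L1") || startsWith(up, "LINE1") || startsWith(up, "LINE-1")) return("L1")
  if (startsWith(up, "SVA")) return("SVA")
  NA_character_
}

.new_me_library <- function(names, classes, sequences) {
  stopifnot(length(names) == length(classes), length(names) == length(sequences))
  lib <- list(
    templates = data.frame(
      name = unname(names),
      me_class = unname(classes),
      sequence = unname(sequences),
      length = unname(nchar(sequences)),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  )
  class(lib) <- "MELibrary"
  lib
}

#' Load a mobile element template library from FASTA
#'
#' Each FASTA record becomes one template. Sequences are uppercased; any
#' character outside `ACGTN` is rejected. The ME class of a record is derived
#' from its header by a case-insensitive prefix rule (`Alu*` -> Alu,
#' `L1*`/`LINE1*` -> L1, `SVA*` -> SVA), overridable per header through
#' `class_map`.
#'
#' @param fasta_path path to a FASTA file, or the string `"builtin"` for the
#'   bundled toy library (see [builtin_me_library()]).
#' @param class_map optional named character vector mapping FASTA headers to
#'   classes in `c("Alu", "L1", "SVA")`; takes precedence over the prefix rule.
#' @return An object of class `MELibrary` with a `templates` data frame
#'   (columns `name`, `me_class`, `sequence`, `length`).
#' @export
load_me_library <- function(fasta_path, class_map = NULL) {
  if (identical(fasta_path, "builtin")) {
    return(builtin_me_library())
  }
  if (!file.exists(fasta_path)) {
    stop("ME library FASTA not found: ", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("empty library: ", fasta_path, " contains no FASTA records")
  }
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate template names in library: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    stop("template '", nm[which(bad)[1]], "' contains non-ACGTN characters")
  }
  if (any(nchar(sq) == 0L)) {
    stop("template '", nm[which(nchar(sq) == 0L)[1]], "' is empty")
  }
  cls <- vapply(nm, .class_from_header, character(1), class_map = class_map)
  if (anyNA(cls)) {
    stop("unclassifiable template: header '", nm[which(is.na(cls))[1]],
         "' matches no class rule and no class_map entry")
  }
  .new_me_library(nm, unname(cls), sq)
}

#' Built-in toy mobile element library
#'
#' Three synthetic templates, one per class, at toy scale: Alu 300 bp,
#' SVA 600 bp, L1 900 bp (L1 is the longest class, mirroring, at reduced
#' scale, the relative lengths of the real elements). Sequences are fixed
#' pseudo-random DNA so tests and the simulator never require a repeat
#' database download. They are synthetic stand-ins, not biological consensus
#' sequences.
#'
#' @return An `MELibrary` with templates `AluY_toy`, `L1_toy`, `SVA_toy`.
#' @export
builtin_me_library <- function() {
  .builtin_library_cache()
}

# Deterministic pseudo-random template sequences, independent of the session
# RNG state (local RNG via a linear congruential generator).
.lcg_dna <- function(n, seed) {
  state <- as.double(seed)
  out <- integer(n)
  for (i in seq_len(n)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    out[i] <- floor(state / 2048) %% 4
  }
  paste(c("A", "C", "G", "T")[out + 1L], collapse = "")
}

.builtin_env <- new.env(parent = emptyenv())

.builtin_library_cache <- function() {
  if (is.null(.builtin_env$lib)) {
    .builtin_env$lib <- .new_me_library(
      names = c("AluY_toy", "L1_toy", "SVA_toy"),
      classes = c("Alu", "L1", "SVA"),
      sequences = c(.lcg_dna(300, 20240301), .lcg_dna(900, 20240302),
                    .lcg_dna(600, 20240303))
    )
  }
  .builtin_env$lib
}

#' Write a template library back to FASTA
#'
#' Sequences are wrapped at 60 columns. Reloading the written file yields an
#' identical library (round-trip).
#'
#' @param lib an `MELibrary`.
#' @param fasta_path output path.
#' @return `fasta_path`, invisibly.
#' @export
write_me_library <- function(lib, fasta_path) {
  stopifnot(inherits(lib, "MELibrary"))
  x <- Biostrings::DNAStringSet(lib$templates$sequence)
  names(x) <- lib$templates$name
  Biostrings::writeXStringSet(x, fasta_path, width = 60L)
  invisible(fasta_path)
}

#' @export
print.MELibrary <- function(x, ...) {
  cat("MELibrary with", nrow(x$templates), "templates:\n")
  print(x$templates[, c("name", "me_class", "length")], row.names = FALSE)
  invisible(x)
}

#' Templates of one class
#' @param lib an `MELibrary`.
#' @param me_class one of `"Alu"`, `"L1"`, `"SVA"`.
#' @return data frame of templates of that class.
#' @keywords internal
templates_of_class <- function(lib, me_class) {
  lib$templates[lib$templates$me_class == me_class, , drop = FALSE]
}
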