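# Open reading frames on circular RNAs: start-codon enumeration with frame
# classification, rolling-circle translation with stop detection, and
# predicted protein masses.

.check_circle_seq <- function(circle_seq) {
  s <- toupper(chartr("Uu", "Tt", circle_seq))
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGU/T characters")
  s
}

.circ_codon <- function(chars, pos, L) {
  # codon starting at 0-based pos, wrapping around the circle
  paste(chars[(pos + 0:2) %% L + 1L], collapse = "")
}

#' Enumerate AUG start codons on a circle
#'
#' Finds every AUG on the circular sequence, wrapping across the back-splice
#' junction, and classifies each start as in frame or out of frame with a
#' tag (or any reference codon position): in frame when the distance from
#' the start to the tag measured along the translation path on the first
#' cycle is a multiple of 3.
#'
#' @param circle_seq The circular RNA sequence in sense orientation (DNA or
#'   RNA alphabet), 5' end at the back-splice acceptor.
#' @param tag_start Optional 0-based position of the tag/reference codon.
#' @return Tibble with `pos` (0-based) and `frame_class`
#'   (`"in_frame_with_tag"` / `"out_of_frame"`, `NA` without a tag).
#' @export
enumerate_start_codons <- function(circle_seq, tag_start = NULL) {
  s <- .check_circle_seq(circle_seq)
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  pos <- which(vapply(
    0:(L - 1), function(p) .circ_codon(chars, p, L) == "ATG", logical(1)
  )) - 1L
  frame_class <- if (is.null(tag_start)) {
    rep(NA_character_, length(pos))
  } else {
    ifelse(((tag_start - pos) %% L) %% 3 == 0,
      "in_frame_with_tag", "out_of_frame"
    )
  }
  tibble::tibble(pos = pos, frame_class = frame_class)
}

#' Frameshift summary of rolling-circle translation
#'
#' Each full pass around a circle of length `L` shifts the reading frame by
#' `L mod 3`; translation is frame-periodic (and can run forever without a
#' stop) only when `L` is divisible by three.
#'
#' @param L Circle length in nucleotides (>= 3).
#' @return List with `L`, `shift_per_cycle`, `periodic`.
#' @export
rolling_circle_frames <- function(L) {
  if (L < 3) stop("circle shorter than one codon")
  list(L = as.integer(L), shift_per_cycle = as.integer(L %% 3), periodic = L %% 3 == 0)
}

#' Rolling-circle translation from one start codon
#'
#' Translates codon by codon around the circle, wrapping at the junction,
#' until a stop codon or until `max_cycles` full passes have been consumed.
#' An unterminated ORF (possible only when `L mod 3 = 0`) is flagged
#' `infinite_orf`.
#'
#' @param circle_seq Circular sequence in sense orientation.
#' @param start_pos 0-based position of the AUG.
#' @param max_cycles Translation budget in full passes (default 4; three
#'   passes restore the frame whenever `L mod 3 != 0`).
#' @return List of class `circ_orf`: `L`, `start_pos`, `peptide`,
#'   `terminated`, `infinite_orf`, `cycles_used`, `mass_kda` (`NA` when the
#'   peptide is empty or unterminated).
#' @export
translate_circular <- function(circle_seq, start_pos, max_cycles = 4L) {
  s <- .check_circle_seq(circle_seq)
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  if (.circ_codon(chars, start_pos, L) != "ATG") {
    stop("start_pos does not hold an AUG codon")
  }
  code <- Biostrings::GENETIC_CODE
  max_codons <- floor(max_cycles * L / 3)
  aas <- character(0)
  terminated <- FALSE
  pos <- start_pos
  consumed <- 0L
  for (i in seq_len(max_codons)) {
    codon <- .circ_codon(chars, pos, L)
    aa <- code[[codon]]
    consumed <- consumed + 3L
    if (aa == "*") {
      terminated <- TRUE
      break
    }
    aas <- c(aas, aa)
    pos <- (pos + 3L) %% L
  }
  peptide <- paste(aas, collapse = "")
  structure(
    list(
      L = L, start_pos = as.integer(start_pos), peptide = peptide,
      terminated = terminated, infinite_orf = !terminated,
      cycles_used = as.integer(ceiling(consumed / L)),
      mass_kda = if (terminated && nchar(peptide) > 0) peptide_mass(peptide) else NA_real_
    ),
    class = "circ_orf"
  )
}

# average-isotope residue masses (Da), monomer minus water
.residue_masses <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Predicted protein mass in kDa
#'
#' Average-isotope residue masses summed plus one water, divided by 1,000 -
#' the quantity compared against apparent sizes on a protein gel.
#'
#' @param peptide Amino-acid string (standard 20 residues).
#' @return Mass in kDa.
#' @export
peptide_mass <- function(peptide) {
  if (nchar(peptide) == 0) stop("empty peptide")
  ch <- strsplit(peptide, "")[[1]]
  unknown <- setdiff(ch, names(.residue_masses))
  if (length(unknown) > 0) stop("unknown residue(s): ", paste(unknown, collapse = ","))
  (sum(.residue_masses[ch]) + 18.01528) / 1000
}
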