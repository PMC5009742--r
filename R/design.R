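#' Reverse complement of a short DNA or RNA sequence
#'
#' RNA inputs (miRNA targets) are complemented into DNA template space
#' (U pairs with A; the complement is written with T), which is how an
#' amplification template carries the reverse complement of an RNA trigger.
#' DNA inputs return DNA.
#'
#' @param seq character scalar over A/C/G/T (DNA) or A/C/G/U (RNA);
#'   case-insensitive.
#' @param alphabet `"DNA"` or `"RNA"`; the alphabet of the *input*.
#' @return Uppercase DNA reverse complement.
#' @export
#' @examples
#' reverse_complement("ACGT")                                # "ACGT"
#' reverse_complement("UGAGGUAGUAGGUUGUAUAGUU", "RNA")       # let-7a -> X'
reverse_complement <- function(seq, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop_input("seq must be a single non-empty string")
  }
  up <- toupper(seq)
  valid <- if (alphabet == "DNA") c("A", "C", "G", "T") else
    c("A", "C", "G", "U")
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% valid)
  if (length(bad) > 0L) {
    stop_input("invalid %s base '%s' at position %d", alphabet,
               chars[bad[1]], bad[1])
  }
  if (alphabet == "RNA") up <- chartr("U", "T", up)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
}

# Nt.BstNBI nicks the top strand of GAGTC(N4) between N4 and N5, i.e. 4 nt
# 3' of the recognition pentamer.
NEASE_TOP_SITE <- "GAGTC"
NEASE_CUT_OFFSET <- 4L

#' Assemble an EXPAR amplification template
#'
#' A standard EXPAR template carries two copies of the target's reverse
#' complement (X') at its 5' and 3' termini, separated by the complement of
#' the nicking-endonuclease recognition site plus a post-cut spacer, so that
#' the extended duplex is nicked exactly at the boundary of the distal
#' trigger copy and releases a trigger-length product. The biotin variant is
#' the same sequence with a biotin recorded at a base near the 5' terminus
#' (lowering the Tm of the inextensible 5'-side duplex); the toehold/biotin
#' variant additionally folds a dumbbell hairpin at the 3' terminus whose
#' invading strand is six bases longer than the incumbent, acting as a
#' thermodynamic filter against near-matched interferents.
#'
#' The shipped construction is a plausible synthetic design: the exact
#' published template sequences are treated as user input.
#'
#' @param target trigger sequence, 5'->3' (typically an RNA miRNA,
#'   18-25 nt).
#' @param kind `"standard"`, `"biotin"`, or `"toehold_biotin"`.
#' @param alphabet alphabet of `target`.
#' @param spacer top-strand post-cut spacer between the recognition site and
#'   the released trigger copy (default `"TCCT"`, 4 nt).
#' @param biotin_position base index of the biotin from the template's 5'
#'   terminus (1-based; default 2).
#' @param incumbent_length length of the hairpin's incumbent strand; the
#'   invading strand is 6 nt longer.
#' @param loop hairpin loop sequence.
#' @param strict error (rather than warn) on targets outside 18-25 nt.
#' @return An object of class `template_design`: `target`, `x_prime`,
#'   `nease_site_complement`, `spacer`, `core` (the standard-template
#'   sequence 5'->3'), `full_template` (core plus any hairpin extension),
#'   `kind`, `biotin_position` (`NA` when untagged), and `toehold` (list
#'   with `invading`, `incumbent`, `loop`, or `NULL`).
#' @export
#' @examples
#' build_template("UGAGGUAGUAGGUUGUAUAGUU", kind = "biotin",
#'                alphabet = "RNA")
build_template <- function(target,
                           kind = c("standard", "biotin", "toehold_biotin"),
                           alphabet = c("RNA", "DNA"),
                           spacer = "TCCT", biotin_position = 2L,
                           incumbent_length = 10L, loop = "TTTT",
                           strict = FALSE) {
  kind <- match.arg(kind)
  alphabet <- match.arg(alphabet)
  len <- nchar(target)
  if (len < 18L || len > 25L) {
    msg <- sprintf("target length %d nt outside the usual 18-25 nt range", len)
    if (strict) stop_input("%s", msg) else warning(msg, call. = FALSE)
  }
  x_prime <- reverse_complement(target, alphabet)
  # core template 5'->3': X' | rc(spacer) | rc(GAGTC) | X'; its reverse
  # complement (the extended top strand) is X | GAGTC | spacer | X, nicked
  # 4 nt past the pentamer so the released fragment is exactly X.
  middle <- reverse_complement(paste0(NEASE_TOP_SITE, toupper(spacer)))
  core <- paste0(x_prime, middle, x_prime)
  biotin_position <- if (kind == "standard") NA_integer_ else
    as.integer(biotin_position)
  if (!is.na(biotin_position) &&
      (biotin_position < 1L || biotin_position > nchar(core))) {
    stop_input("biotin_position %d outside template (1-%d)",
               biotin_position, nchar(core))
  }
  toehold <- NULL
  full <- core
  if (kind == "toehold_biotin") {
    invading_length <- incumbent_length + 6L
    if (invading_length > nchar(x_prime)) {
      stop_input("incumbent_length + 6 exceeds the trigger-complement length")
    }
    tail_inc <- substr(core, nchar(core) - incumbent_length + 1L, nchar(core))
    invading <- substr(core, nchar(core) - invading_length + 1L, nchar(core))
    incumbent <- reverse_complement(tail_inc)
    toehold <- list(invading = invading, incumbent = incumbent,
                    loop = toupper(loop))
    full <- paste0(core, toehold$loop, incumbent)
  }
  structure(list(target = toupper(target), alphabet = alphabet,
                 x_prime = x_prime,
                 nease_site_complement = reverse_complement(NEASE_TOP_SITE),
                 spacer = toupper(spacer), core = core, full_template = full,
                 kind = kind, biotin_position = biotin_position,
                 toehold = toehold),
            class = "template_design")
}

#' @export
print.template_design <- function(x, ...) {
  cat(sprintf("<template_design> %s template for %d-nt target\n",
              x$kind, nchar(x$target)))
  cat(sprintf("  target (%s 5'->3'): %s\n", x$alphabet, x$target))
  cat(sprintf("  template (DNA 5'->3'): %s\n", x$full_template))
  if (!is.na(x$biotin_position)) {
    cat(sprintf("  biotin at base %d from the 5' terminus\n",
                x$biotin_position))
  }
  if (!is.null(x$toehold)) {
    cat(sprintf("  toehold hairpin: invading %d nt / incumbent %d nt (loop %s)\n",
                nchar(x$toehold$invading), nchar(x$toehold$incumbent),
                x$toehold$loop))
  }
  invisible(x)
}

#' Validate the nicking site of an assembled template
#'
#' Scans the top strand of the template's extended duplex (the reverse
#' complement of the core template) for the Nt.BstNBI recognition pentamer
#' and checks that exactly one site is present, positioned so that the nick
#' (4 nt downstream of the pentamer) releases a product of exactly the
#' trigger's length.
#'
#' @param design a [build_template()] result.
#' @return A list with `ok` (logical), `n_sites`, `cut_offset` (distance of
#'   the nick from the top strand's 5' end, `NA` unless exactly one site),
#'   `released_length`, and `findings` (character vector of failures; empty
#'   when valid).
#' @export
validate_nease_site <- function(design) {
  stopifnot(inherits(design, "template_design"))
  top <- reverse_complement(design$core)
  hits <- gregexpr(NEASE_TOP_SITE, top, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  n_sites <- length(hits)
  findings <- character(0)
  cut_offset <- NA_integer_
  released <- NA_integer_
  if (n_sites == 0L) {
    findings <- c(findings, "no recognition site on the extended top strand")
  } else if (n_sites > 1L) {
    findings <- c(findings,
                  sprintf("%d recognition sites found; exactly 1 required",
                          n_sites))
  } else {
    cut_offset <- hits[1] + nchar(NEASE_TOP_SITE) - 1L + NEASE_CUT_OFFSET
    released <- nchar(top) - cut_offset
    if (released != nchar(design$target)) {
      findings <- c(findings,
                    sprintf("nick releases %d nt, trigger is %d nt",
                            released, nchar(design$target)))
    }
  }
  list(ok = length(findings) == 0L, n_sites = n_sites,
       cut_offset = cut_offset, released_length = released,
       findings = findings)
}

# Unified DNA/DNA nearest-neighbor parameters: dH kcal/mol, dS cal/(mol K),
# keyed by the top-strand dinucleotide of each stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # terminal pair class
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_CONSTANT_CAL <- 1.987             # cal/(mol K)

#' Nearest-neighbor melting temperature of a short DNA duplex
#'
#' Accumulates unified DNA/DNA nearest-neighbor enthalpies and entropies
#' over the base-pair stacks of the duplex formed by `strandA` and
#' `strandB`, with terminal initiation terms, an entropic salt correction
#' (`0.368 * (N - 1) * ln[Na+]`), and the two-state relation
#' `Tm = dH / (dS + R ln(C_T / 4)) - 273.15`. Stacks flanking mismatched
#' positions contribute nothing, so any internal mismatch destabilises the
#' duplex. Intended for ranking candidate designs, not for reproducing
#' measured Tm values (template/trigger hybrids may be RNA/DNA).
#'
#' @param strandA top strand, DNA 5'->3'.
#' @param strandB bottom strand, DNA 5'->3' (paired antiparallel with
#'   `strandA`; same length, fully or nearly complementary).
#' @param strand_conc total single-strand concentration C_T, molar.
#' @param monovalent_salt monovalent cation concentration, molar.
#' @return Predicted Tm, degrees C.
#' @export
#' @examples
#' a <- "TGAGGTAGTAGGTTGTATAGTT"
#' nn_duplex_tm(a, reverse_complement(a))
nn_duplex_tm <- function(strandA, strandB, strand_conc = 2.5e-7,
                         monovalent_salt = 0.05) {
  if (strand_conc <= 0 || monovalent_salt <= 0) {
    stop_input("strand_conc and monovalent_salt must be positive")
  }
  a <- strsplit(toupper(strandA), "", fixed = TRUE)[[1]]
  # align antiparallel: position i of A pairs with position N+1-i of B
  b <- rev(strsplit(toupper(strandB), "", fixed = TRUE)[[1]])
  if (length(a) != length(b)) {
    stop_input("strands must have equal length (got %d and %d)",
               length(a), length(b))
  }
  if (length(a) > 60L) stop_input("duplex longer than 60 nt not supported")
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  if (any(!a %in% names(comp)) || any(!b %in% names(comp))) {
    stop_input("strands must be DNA over A/C/G/T")
  }
  matched <- comp[a] == b
  n <- length(a)
  n_stacks <- 0L
  dH <- 0
  dS <- 0
  for (i in seq_len(n - 1L)) {
    if (matched[i] && matched[i + 1L]) {
      key <- paste0(a[i], a[i + 1L])
      dH <- dH + NN_DH[[key]]
      dS <- dS + NN_DS[[key]]
      n_stacks <- n_stacks + 1L
    }
  }
  if (n_stacks < 4L) {
    stop_input("no complementary core: only %d matched stacks", n_stacks)
  }
  for (i in c(1L, n)) {
    if (matched[i]) {
      cls <- if (a[i] %in% c("G", "C")) "GC" else "AT"
      dH <- dH + NN_INIT_DH[[cls]]
      dS <- dS + NN_INIT_DS[[cls]]
    }
  }
  dS_salt <- dS + 0.368 * (n - 1) * log(monovalent_salt)
  tm_k <- dH * 1000 / (dS_salt + GAS_CONSTANT_CAL * log(strand_conc / 4))
  tm_k - 273.15
}
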