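# Substitution-class systems.
#
# SSB7 collapses the 12 directed single-base changes onto six
# pyrimidine/adenine-referenced labels via reverse complement, plus one
# separate class for any change whose reference base sits in a CpG
# dinucleotide (on either strand). SSB192 keeps the full pyrimidine-centred
# trinucleotide context and the strand: 6 substitutions x 16 flanking
# contexts x 2 strands.

#' SSB7 class labels
#'
#' The seven substitution classes: `A>T`, `A>C`, `A>G`, `C>A`, `C>T`, `C>G`
#' and `CpG>N` (any change at a CpG site, regardless of the alternate
#' allele).
#' @return Character vector of length 7.
#' @export
ssb7_classes <- function() {
  c("A>T", "A>C", "A>G", "C>A", "C>T", "C>G", "CpG>N")
}

# lookup: collapsed (ref, alt) integer codes -> class index 1..6
.C7MAP <- matrix(NA_integer_, 4L, 4L)
.C7MAP[1L, 4L] <- 1L # A>T
.C7MAP[1L, 2L] <- 2L # A>C
.C7MAP[1L, 3L] <- 3L # A>G
.C7MAP[2L, 1L] <- 4L # C>A
.C7MAP[2L, 4L] <- 5L # C>T
.C7MAP[2L, 3L] <- 6L # C>G

# Integer-coded SSB7 classification. five/three may be NA (unknown neighbour,
# treated as non-CpG). Vectorised; no input validation.
.class7_int <- function(ref, alt, five, three) {
  pur <- ref == 3L | ref == 4L # G or T: map through reverse complement
  r <- ref; a <- alt; t3 <- three
  if (any(pur)) {
    r[pur] <- .COMP[ref[pur]]
    a[pur] <- .COMP[alt[pur]]
    f <- five[pur]
    t3[pur] <- ifelse(is.na(f), NA_integer_, .COMP[f])
  }
  out <- .C7MAP[cbind(r, a)]
  cpg <- r == 2L & !is.na(t3) & t3 == 3L
  out[cpg] <- 7L
  out
}

# Integer-coded SSB192 classification -> index in [0, 192). Neighbours must
# be known. Layout: strand*96 + (sub-1)*16 + (five-1)*4 + (three-1), where
# sub indexes C>A, C>G, C>T, T>A, T>C, T>G on the pyrimidine-centred form and
# strand is 0 when the coding-strand reference is already a pyrimidine.
.SUBMAP <- matrix(NA_integer_, 4L, 4L)
.SUBMAP[2L, 1L] <- 1L # C>A
.SUBMAP[2L, 3L] <- 2L # C>G
.SUBMAP[2L, 4L] <- 3L # C>T
.SUBMAP[4L, 1L] <- 4L # T>A
.SUBMAP[4L, 2L] <- 5L # T>C
.SUBMAP[4L, 3L] <- 6L # T>G

.class192_int <- function(ref, alt, five, three) {
  pur <- ref == 1L | ref == 3L # A or G: complement to pyrimidine-centred
  r <- ref; a <- alt; f <- five; t3 <- three
  if (any(pur)) {
    r[pur] <- .COMP[ref[pur]]
    a[pur] <- .COMP[alt[pur]]
    f[pur] <- .COMP[three[pur]]
    t3[pur] <- .COMP[five[pur]]
  }
  sub <- .SUBMAP[cbind(r, a)]
  as.integer(pur) * 96L + (sub - 1L) * 16L + (f - 1L) * 4L + (t3 - 1L)
}

.check_bases <- function(ref, alt) {
  if (anyNA(ref) || anyNA(alt)) {
    ssb_stop("ref/alt bases must be one of A, C, G, T", "ssb_invalid_base")
  }
  if (any(ref == alt)) {
    ssb_stop("ref and alt allele are identical", "ssb_invalid_substitution")
  }
}

.neighbor_int <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "N" | x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% .BASES)
  if (any(bad)) ssb_stop("neighbour bases must be A, C, G, T or unknown",
                         "ssb_invalid_base")
  .base_int(x)
}

#' Classify a substitution into the seven SSB7 classes
#'
#' Purine references are collapsed through the reverse complement
#' (`T>x` is `A>comp(x)`, `G>x` is `C>comp(x)`). Any change whose reference
#' base is the C of a 5'-CpG-3' dinucleotide on either strand is `CpG>N`
#' regardless of the alternate allele. Unknown neighbours (sequence
#' boundaries) are treated as non-CpG.
#'
#' @param ref,alt Reference and alternate base (vectors of "A","C","G","T").
#' @param five_prime,three_prime Neighbouring bases on the coding strand;
#'   `NA` or `"N"` when unknown.
#' @return Character vector of class labels (see [ssb7_classes()]).
#' @examples
#' classify_substitution7("A", "G", "C", "C") # "A>G"
#' classify_substitution7("C", "T", "A", "G") # "CpG>N"
#' @export
classify_substitution7 <- function(ref, alt, five_prime = NA,
                                   three_prime = NA) {
  ref <- .base_int(toupper(ref)); alt <- .base_int(toupper(alt))
  .check_bases(ref, alt)
  n <- length(ref)
  five <- rep_len(.neighbor_int(five_prime), n)
  three <- rep_len(.neighbor_int(three_prime), n)
  ssb7_classes()[.class7_int(ref, alt, five, three)]
}

#' Classify a substitution into the 192 context-and-strand classes
#'
#' Returns an integer index in `[0, 192)` encoding the pyrimidine-centred
#' substitution, the two flanking bases and the strand flag (whether the
#' coding-strand reference had to be complemented). The mapping is a
#' bijection over all (substitution, context, strand) triples.
#'
#' @inheritParams classify_substitution7
#' @return Integer vector of class indices in `[0, 192)`.
#' @export
classify_substitution192 <- function(ref, alt, five_prime, three_prime) {
  ref <- .base_int(toupper(ref)); alt <- .base_int(toupper(alt))
  .check_bases(ref, alt)
  n <- length(ref)
  five <- rep_len(.neighbor_int(five_prime), n)
  three <- rep_len(.neighbor_int(three_prime), n)
  if (anyNA(five) || anyNA(three)) {
    ssb_stop("sequence context unavailable for SSB192 classification",
             "ssb_context_unavailable")
  }
  .class192_int(ref, alt, five, three)
}
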