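# Restriction enzymes with IUPAC-degenerate recognition sites.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Define a restriction enzyme
#'
#' An enzyme is its recognition site (IUPAC nucleotide codes allowed) plus the
#' cut offset: the number of bases from the start of a site match, on the top
#' strand, at which the phosphodiester backbone is cut. For example EcoRI
#' (G^AATTC) has offset 1 and NlaIII (CATG^) has offset 4.
#'
#' @param name Enzyme name, e.g. `"EcoRI"`.
#' @param site Recognition site as IUPAC nucleotide text, e.g. `"GCWGC"`.
#' @param cut_offset Integer in `[0, nchar(site)]`: top-strand cut position
#'   relative to the start of a site match.
#' @return An object of class `gbs_enzyme`.
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
#' @seealso [builtin_enzymes()], [find_cut_positions()]
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(as.character(site))
  if (nchar(site) < 1L) stop("recognition site must be non-empty")
  letters <- strsplit(site, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in recognition site: ", paste(bad, collapse = ", "))
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie in [0, nchar(site)]")
  }
  structure(
    list(name = as.character(name), site = site, cut_offset = cut_offset),
    class = "gbs_enzyme"
  )
}

#' @export
print.gbs_enzyme <- function(x, ...) {
  cut_mark <- paste0(
    substr(x$site, 1, x$cut_offset), "^",
    substr(x$site, x$cut_offset + 1L, nchar(x$site))
  )
  cat(sprintf("<gbs_enzyme> %s  %s\n", x$name, cut_mark))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' The five enzymes commonly assessed for two-enzyme GBS library design:
#' EcoRI (G^AATTC), NlaIII (CATG^), PstI (CTGCA^G), ApeKI (G^CWGC) and
#' BstNI (CC^WGG). All five sites are palindromic under IUPAC-aware reverse
#' complement, so top-strand cut positions describe both strands.
#'
#' @return Named list of [enzyme()] objects.
#' @export
builtin_enzymes <- function() {
  list(
    EcoRI  = enzyme("EcoRI",  "GAATTC", 1L),
    NlaIII = enzyme("NlaIII", "CATG",   4L),
    PstI   = enzyme("PstI",   "CTGCAG", 5L),
    ApeKI  = enzyme("ApeKI",  "GCWGC",  1L),
    BstNI  = enzyme("BstNI",  "CCWGG",  2L)
  )
}

#' Resolve an enzyme by name or pass a `gbs_enzyme` through
#'
#' @param x A `gbs_enzyme` or the name of a built-in enzyme.
#' @return A `gbs_enzyme`.
#' @export
get_enzyme <- function(x) {
  if (inherits(x, "gbs_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) {
    enz <- builtin_enzymes()[[x]]
    if (is.null(enz)) {
      stop("unknown enzyme '", x, "'; built-ins are: ",
           paste(names(builtin_enzymes()), collapse = ", "))
    }
    return(enz)
  }
  stop("expected a gbs_enzyme or a built-in enzyme name")
}
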