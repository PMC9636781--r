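# Internal helpers shared across modules.

# IUPAC degenerate codes, keyed by the sorted concatenation of the base set.
.IUPAC_BY_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N"
)

# base set for each IUPAC code
.SET_BY_IUPAC <- local({
  s <- strsplit(names(.IUPAC_BY_SET), "")
  names(s) <- unname(.IUPAC_BY_SET)
  s
})

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_BY_SET[[key]]
  if (is.null(code)) stop("not a DNA base set: ", key)
  code
}

iupac_bases <- function(code) {
  s <- .SET_BY_IUPAC[[code]]
  if (is.null(s)) stop("not an IUPAC code: ", code)
  s
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` plus the degenerate
#' IUPAC codes (delegated to Biostrings).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. All generators route through this so
# they are pure functions of their specs and seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a component sub-seed so that independent simulation components
# (intrinsic landscape, MTase draws, coverage) consume independent streams.
# Keeping the intrinsic stream separate makes the intrinsic landscape of a
# genome identical whether or not an MTase is simulated on top of it.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483629L) + 1L
}

# Per-site methylation level; NA where there is no read support.
meth_level <- function(meth, unmeth) {
  tot <- meth + unmeth
  ifelse(tot > 0, meth / tot, NA_real_)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
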