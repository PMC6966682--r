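# Shared constants and small helpers.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes for the 20 proteinogenic amino acids, the
#' residue universe for all peptides handled by the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# TCR-oriented peptide positions of a 9-mer (the remaining positions face
# the MHC groove).
TCR_POSITIONS <- c(1L, 4L, 5L, 8L)

#' Extract the HLA locus from a class-I allele name
#'
#' @param allele Character vector of allele names such as `"HLA-A*02:01"`
#'   or `"A*02:01"`.
#' @return Character vector with values `"A"`, `"B"` or `"C"`.
#' @examples
#' hla_locus(c("HLA-A*02:01", "B*07:02"))
#' @export
hla_locus <- function(allele) {
  locus <- stringr::str_match(allele, "^(?:HLA-)?([ABC])\\*")[, 2]
  if (anyNA(locus)) {
    bad <- unique(allele[is.na(locus)])
    rlang::abort(paste0("cannot parse HLA locus from allele name(s): ",
                        paste(bad, collapse = ", ")),
                 class = "neosurv_format_error")
  }
  locus
}

# Deterministic 32-bit string hash (FNV-1a), used to derive per-allele RNG
# seeds so predictor profiles depend only on the allele name and a base seed.
str_hash <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(s)
    h <- 2166136261 %% 2147483647
    for (b in bytes) {
      h <- bitwXor(h, b)
      h <- (h * 16777619) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
# One call per logical component gives each component its own stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a component seed from a master seed; kept below 2^31 - 1.
# The seed digits are hashed together with the component name: linearly
# related derived seeds (master*k + offset) give poorly separated
# Mersenne-Twister initial states and measurably correlated streams,
# so the mixing must be nonlinear in the master seed.
component_seed <- function(seed, component) {
  str_hash(paste0(component, ":", format(seed, scientific = FALSE)))
}

assert_peptide9 <- function(x, arg = "peptide") {
  bad <- nchar(x) != 9L
  if (any(bad)) {
    rlang::abort(
      paste0(arg, " must be a 9-mer; got length ",
             paste(unique(nchar(x[bad])), collapse = ", ")),
      class = "neosurv_length_error"
    )
  }
  chars <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  unknown <- setdiff(chars, AA_ALPHABET)
  if (length(unknown)) {
    rlang::abort(paste0(arg, " contains non-standard residues: ",
                        paste(unknown, collapse = ", ")),
                 class = "neosurv_format_error")
  }
  invisible(x)
}
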