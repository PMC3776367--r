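#' Molecular fingerprint from a SMILES string
#'
#' Computes a fixed-length binary fingerprint for one molecule given as a
#' SMILES line notation. The molecule is parsed and its atom-pair
#' descriptors computed with ChemmineR; each descriptor code is then
#' folded onto a bit position by a Lehmer-style scramble modulo the
#' Mersenne prime 2^31 - 1 before reduction to `nbits` (plain modulo
#' would collide systematically, as atom-pair codes carry the topological
#' distance in their low bits). Folding keeps the fingerprint total for
#' arbitrarily small or unusual molecules at the cost of occasional bit
#' collisions. Deterministic for a given SMILES and `nbits`.
#'
#' @param smiles SMILES string.
#' @param nbits Fingerprint length in bits (default 512).
#' @return Object of class `fingerprint`: list with `bits` (sorted integer
#'   positions of the set bits, 1-based), `nbits`.
#' @export
fingerprint_from_smiles <- function(smiles, nbits = 512) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("the fingerprint backend requires the ChemmineR package")
  }
  bits <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(mol = smiles)))
    junk <- utils::capture.output(
      ap <- suppressWarnings(ChemmineR::sdf2ap(sdf)), type = "message")
    codes <- ChemmineR::ap(ap)[[1]]
    # exact in doubles: codes < 2^53, (code mod M) * 48271 < 2^47
    m31 <- 2147483647
    scrambled <- ((codes %% m31) * 48271) %% m31
    as.integer(scrambled %% nbits) + 1L
  }, error = function(e) {
    stop("structure error: cannot fingerprint SMILES '", smiles, "': ",
         conditionMessage(e), call. = FALSE)
  })
  structure(list(bits = sort(unique(bits)), nbits = as.integer(nbits)),
            class = "fingerprint")
}

#' Tanimoto coefficient of two fingerprints
#'
#' The standard binary molecular similarity: shared bits over total bits,
#' \eqn{|A \cap B| / |A \cup B|}. Two empty fingerprints compare as 1.0;
#' an empty against a non-empty as 0.0.
#'
#' @param a,b Fingerprints from [fingerprint_from_smiles()], computed with
#'   the same `nbits`.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits) {
    stop("fingerprint parameter mismatch: ", a$nbits, " vs ", b$nbits, " bits")
  }
  if (length(a$bits) == 0L && length(b$bits) == 0L) return(1)
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(a$bits) + length(b$bits) - inter
  if (uni == 0L) 0 else inter / uni
}

#' Structural-similarity provider from SMILES structures
#'
#' Builds a similarity provider backed by molecular fingerprints: every
#' drug's SMILES is fingerprinted once and pairs are compared with the
#' [tanimoto()] coefficient, giving \eqn{Q^s \in [0, 1]}. Drugs whose
#' SMILES cannot be parsed degrade to similarity 0 against everything
#' (with a warning), keeping the pipeline total; so do drugs missing from
#' `smiles_map`.
#'
#' @param smiles_map Named character vector mapping drug identifier to
#'   SMILES, as from [read_smiles()].
#' @param nbits Fingerprint length (default 512).
#' @return Object of class `similarity_provider` (backend `"fingerprint"`).
#' @export
fingerprint_provider <- function(smiles_map, nbits = 512) {
  fps <- vector("list", length(smiles_map))
  names(fps) <- names(smiles_map)
  for (id in names(smiles_map)) {
    fps[[id]] <- tryCatch(fingerprint_from_smiles(smiles_map[[id]], nbits),
                          error = function(e) {
                            warning("drug ", id, " degrades to similarity 0: ",
                                    conditionMessage(e))
                            NULL
                          })
  }
  lookup <- function(a, b) {
    fa <- fps[[as.character(a)]]
    fb <- fps[[as.character(b)]]
    if (is.null(fa) || is.null(fb)) return(0)
    tanimoto(fa, fb)
  }
  structure(list(fun = lookup, backend = "fingerprint", nbits = nbits),
            class = "similarity_provider")
}

#' Structural-similarity provider from a precomputed table
#'
#' Serves pairwise similarity scores from an externally computed table
#' (e.g. an Open Babel run), allowing bit-exact reuse. The table must be
#' symmetric within 1e-9 where both directions are present, with all scores
#' in \[0, 1\]; absent pairs score 0.
#'
#' @param table data.frame with columns `drug_a`, `drug_b`, `score`, as
#'   from [read_similarity_table()].
#' @return Object of class `similarity_provider` (backend `"precomputed"`).
#' @export
precomputed_provider <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("drug_a", "drug_b", "score") %in% names(table)))
  a <- as.character(table$drug_a)
  b <- as.character(table$drug_b)
  s <- as.numeric(table$score)
  if (any(is.na(s)) || any(s < 0) || any(s > 1)) {
    stop("validation error: similarity scores must lie in [0, 1]")
  }
  env <- new.env(parent = emptyenv(), size = 2L * length(s))
  put <- function(x, y, v) {
    key <- paste(x, y, sep = "\r")
    old <- env[[key]]
    if (!is.null(old) && abs(old - v) > 1e-9) {
      stop("validation error: asymmetric similarity for pair (", x, ", ", y,
           "): ", old, " vs ", v)
    }
    env[[key]] <- v
  }
  for (i in seq_along(s)) {
    put(a[i], b[i], s[i])
    put(b[i], a[i], s[i])
  }
  lookup <- function(x, y) {
    v <- env[[paste(x, y, sep = "\r")]]
    if (is.null(v)) 0 else v
  }
  structure(list(fun = lookup, backend = "precomputed"),
            class = "similarity_provider")
}

#' Query a similarity provider
#'
#' @param provider A `similarity_provider`.
#' @param a,b Drug identifiers.
#' @return \eqn{Q^s(a, b) \in [0, 1]}; symmetric.
#' @export
sim_score <- function(provider, a, b) {
  stopifnot(inherits(provider, "similarity_provider"))
  provider$fun(as.character(a), as.character(b))
}

#' @export
print.similarity_provider <- function(x, ...) {
  cat("<similarity_provider> backend: ", x$backend, "\n", sep = "")
  invisible(x)
}
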