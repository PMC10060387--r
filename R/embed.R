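#' Embedding models
#'
#' Spectral similarity in this package is computed as the cosine of two
#' fixed-length spectrum embeddings. Trained neural ("primary" role, the
#' coarse high-recall scorer used for candidate preselection) and
#' word-embedding ("secondary" role, feature 1 of the ranker) models plug
#' in through the same contract: an object with a name, a role, a
#' dimensionality and a deterministic `embed(spectrum)` function. The
#' package ships deterministic binned reference embedders for both roles
#' so the whole pipeline runs without any trained model file.
#'
#' @name embedding-models
NULL

new_embedding_model <- function(name, role, dim, params, embed_fun,
                                ionmode = NULL) {
  .assert(role %in% c("primary_similarity", "secondary_similarity"),
          "role must be primary_similarity or secondary_similarity")
  counter <- new.env(parent = emptyenv())
  counter$calls <- 0L
  structure(list(name = name, role = role, dim = as.integer(dim),
                 params = params, embed_fun = embed_fun,
                 ionmode = ionmode, counter = counter),
            class = "ms2_embedding_model")
}

#' @exportS3Method base::print
print.ms2_embedding_model <- function(x, ...) {
  cat(sprintf("<ms2_embedding_model %s> role=%s dim=%d\n",
              x$name, x$role, x$dim))
  invisible(x)
}

#' Deterministic binned reference embedder
#'
#' Maps a spectrum to an L2-normalised vector of per-bin summed
#' `intensity^intensity_power` values over fixed m/z bins. A coarse
#' binning (1 Da) serves as the primary-similarity stand-in, a finer one
#' (0.1 Da) as the secondary-similarity stand-in. Not a trained model:
#' it orders spectral similarity sensibly but has none of the learned
#' generalisation of a neural embedder.
#'
#' @param bin_width bin width in Da (default 1.0).
#' @param max_mz upper m/z bound in Da (default 1000, the library cleaning
#'   cut-off).
#' @param intensity_power exponent applied to intensities before binning
#'   (default 0.5, damping dominant base peaks).
#' @param role embedding role (default `"primary_similarity"`).
#' @return an `ms2_embedding_model`.
#' @export
reference_binned_embedder <- function(bin_width = 1.0, max_mz = 1000,
                                      intensity_power = 0.5,
                                      role = "primary_similarity") {
  .assert(bin_width > 0, "bin_width must be positive")
  dim <- as.integer(ceiling(max_mz / bin_width))
  params <- list(type = "binned", bin_width = bin_width, max_mz = max_mz,
                 intensity_power = intensity_power)
  embed_fun <- function(s) {
    bins <- pmin(floor(s$mz / bin_width) + 1L, dim)
    v <- numeric(dim)
    w <- s$intensity^intensity_power
    agg <- rowsum(w, group = bins)
    v[as.integer(rownames(agg))] <- agg
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    v
  }
  new_embedding_model(
    name = sprintf("binned_%gDa_p%g", bin_width, intensity_power),
    role = role, dim = dim, params = params, embed_fun = embed_fun)
}

# Rebuild a reference embedder from its serialized parameter list.
model_from_params <- function(params, role) {
  .assert(identical(params$type, "binned"),
          "only binned reference embedders can be rebuilt from parameters")
  reference_binned_embedder(bin_width = params$bin_width,
                            max_mz = params$max_mz,
                            intensity_power = params$intensity_power,
                            role = role)
}

#' Embed one spectrum
#'
#' @param model an `ms2_embedding_model`.
#' @param s a cleaned [ms2_spectrum].
#' @return numeric vector of length `model$dim`; repeated calls are
#'   identical.
#' @export
embed_spectrum <- function(model, s) {
  .assert(inherits(model, "ms2_embedding_model"), "not an embedding model")
  if (!is.null(model$ionmode) && s$ionmode != model$ionmode) {
    stop(sprintf("ionmode mismatch: model is %s, spectrum %s is %s",
                 model$ionmode, s$spectrum_id, s$ionmode), call. = FALSE)
  }
  model$counter$calls <- model$counter$calls + 1L
  v <- model$embed_fun(s)
  .assert(length(v) == model$dim && all(is.finite(v)),
          "embedder returned a malformed vector")
  v
}

#' Embed a list of spectra into a matrix
#'
#' @param model an `ms2_embedding_model`.
#' @param spectra list of cleaned spectra.
#' @return numeric matrix, one row per spectrum, `model$dim` columns.
#' @export
embed_matrix <- function(model, spectra) {
  out <- matrix(0, nrow = length(spectra), ncol = model$dim)
  for (i in seq_along(spectra)) out[i, ] <- embed_spectrum(model, spectra[[i]])
  rownames(out) <- vapply(spectra, function(s) s$spectrum_id, character(1))
  out
}

#' Cosine similarity of two embeddings
#'
#' @param va,vb numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return `dot(va, vb) / (|va| |vb|)`, clipped to `[-1, 1]`.
#' @export
embedding_similarity <- function(va, vb) {
  .assert(length(va) == length(vb), "embedding dimensions differ")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0)
    stop("cannot compute cosine similarity of a zero vector", call. = FALSE)
  max(-1, min(1, sum(va * vb) / (na * nb)))
}

# ---- cosine-type peak-matching scores -------------------------------------

# Collect admissible peak pairs, order by intensity product (desc, ties by
# indices), accept greedily one-to-one, and normalise by the full intensity
# norms. `shift` adds precursor-difference-shifted matches (modified
# cosine); a pair admissible both directly and via shift counts once, as a
# direct match.
.greedy_cosine <- function(sa, sb, tolerance, shift) {
  ia <- sa$intensity; ib <- sb$intensity
  d <- outer(sa$mz, sb$mz, "-")
  direct <- abs(d) <= tolerance
  pairs <- which(direct, arr.ind = TRUE)
  kind <- rep("direct", nrow(pairs))
  if (shift) {
    delta <- sa$precursor_mz - sb$precursor_mz
    shifted <- abs(d - delta) <= tolerance & !direct
    sp <- which(shifted, arr.ind = TRUE)
    pairs <- rbind(pairs, sp)
    kind <- c(kind, rep("precursor-shifted", nrow(sp)))
  }
  if (nrow(pairs) == 0) {
    return(list(score = 0,
                matches = data.frame(index_a = integer(0),
                                     index_b = integer(0),
                                     contribution = numeric(0),
                                     kind = character(0))))
  }
  prod <- ia[pairs[, 1]] * ib[pairs[, 2]]
  o <- order(-prod, pairs[, 1], pairs[, 2])
  used_a <- logical(length(ia)); used_b <- logical(length(ib))
  keep <- integer(0)
  for (r in o) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE
      keep <- c(keep, r)
    }
  }
  contrib <- prod[keep] / (sqrt(sum(ia^2)) * sqrt(sum(ib^2)))
  list(score = sum(contrib),
       matches = data.frame(index_a = as.integer(pairs[keep, 1]),
                            index_b = as.integer(pairs[keep, 2]),
                            contribution = contrib,
                            kind = kind[keep],
                            stringsAsFactors = FALSE))
}

#' Greedy cosine similarity between two spectra
#'
#' Peaks within `tolerance` Da are candidate matches; pairs are accepted
#' greedily in order of descending intensity product under a one-to-one
#' constraint. The score is the sum of matched intensity products divided
#' by the product of the full intensity-vector norms, hence in `[0, 1]`.
#'
#' @param sa,sb cleaned spectra.
#' @param tolerance fragment mass tolerance in Da (default 0.05).
#' @return list with `score` and `matches` (data.frame `index_a`,
#'   `index_b`, `contribution`, `kind`).
#' @export
cosine_greedy <- function(sa, sb, tolerance = 0.05) {
  .greedy_cosine(sa, sb, tolerance, shift = FALSE)
}

#' Modified cosine similarity between two spectra
#'
#' Like [cosine_greedy()], but peak pairs are also admissible when they
#' match after shifting by the precursor m/z difference of the two
#' spectra (neutral-loss matching). A pair admissible both ways counts
#' once, as a direct match.
#'
#' @inheritParams cosine_greedy
#' @return list with `score` and `matches`.
#' @export
modified_cosine <- function(sa, sb, tolerance = 0.05) {
  .assert(!is.na(sa$precursor_mz) && !is.na(sb$precursor_mz),
          "modified cosine requires precursor m/z on both spectra")
  .greedy_cosine(sa, sb, tolerance, shift = TRUE)
}
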