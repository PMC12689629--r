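# Spectrum preprocessing and modified-cosine similarity with
# precursor-shift-aware peak pairing; analog search and two-tier library
# search built on top of it.

.as_spec <- function(s) {
  if (is.data.frame(s) && "peaks" %in% names(s)) {
    if (nrow(s) != 1L) stop("expected a single spectrum", call. = FALSE)
    list(spectrum_id = if ("spectrum_id" %in% names(s)) s$spectrum_id else NA,
         precursor_mz = s$precursor_mz, peaks = s$peaks[[1]])
  } else if (is.list(s) && all(c("precursor_mz", "peaks") %in% names(s))) {
    if (is.null(s$spectrum_id)) s$spectrum_id <- NA_character_
    s
  } else {
    stop("a spectrum must be a one-row spectra tibble or a list with ",
         "precursor_mz and peaks", call. = FALSE)
  }
}

.preprocess_peaks <- function(pk, precursor, precursor_exclusion, window,
                              top_k) {
  pk <- pk[abs(pk$mz - precursor) > precursor_exclusion, , drop = FALSE]
  if (!nrow(pk)) return(pk)
  keep <- vapply(seq_len(nrow(pk)), function(i) {
    inwin <- abs(pk$mz - pk$mz[i]) <= window
    # peak survives if among the top_k most intense within its own window
    sum(pk$intensity[inwin] > pk$intensity[i]) < top_k
  }, logical(1))
  pk <- pk[keep, , drop = FALSE]
  pk[order(pk$mz), , drop = FALSE]
}

#' Preprocess MS/MS spectra for library matching
#'
#' Removes fragments within `±precursor_exclusion` Da of the precursor m/z
#' and keeps, for every peak, only those ranking among the `top_k` most
#' intense fragments within its own `±window` Da neighborhood.
#'
#' @param x A spectra tibble (MS level 2).
#' @param precursor_exclusion Width of the precursor exclusion zone, Da.
#' @param window Half-width of the sliding intensity-rank window, Da.
#' @param top_k Number of peaks retained per window.
#' @return The spectra tibble with filtered peak lists (possibly empty).
#' @export
preprocess_spectra <- function(x, precursor_exclusion = 17, window = 50,
                               top_k = 6L) {
  x <- validate_spectra(x)
  x$peaks <- purrr::map2(x$peaks, x$precursor_mz, .preprocess_peaks,
                         precursor_exclusion = precursor_exclusion,
                         window = window, top_k = top_k)
  x
}

# Eligible peak pairs between two peak lists given a precursor shift:
# direct (|mz_a - mz_b| <= tol) or shifted (|mz_b - mz_a - shift| <= tol).
# Weights are products of the scaled, normalized intensities.
.eligible_pairs <- function(pka, pkb, shift, frag_tol, scaling) {
  wa <- if (scaling == "sqrt") sqrt(pka$intensity) else pka$intensity
  wb <- if (scaling == "sqrt") sqrt(pkb$intensity) else pkb$intensity
  na_ <- sqrt(sum(wa^2)); nb_ <- sqrt(sum(wb^2))
  if (na_ == 0 || nb_ == 0) {
    return(list(pairs = NULL, wa = wa, wb = wb, na = na_, nb = nb_))
  }
  d_direct <- abs(outer(pka$mz, pkb$mz, function(a, b) a - b))
  ok_direct <- d_direct <= frag_tol
  d_shift <- abs(outer(pka$mz, pkb$mz, function(a, b) b - a - shift))
  ok_shift <- d_shift <= frag_tol & abs(shift) > frag_tol
  any_ok <- ok_direct | ok_shift
  if (!any(any_ok)) {
    return(list(pairs = NULL, wa = wa, wb = wb, na = na_, nb = nb_))
  }
  idx <- which(any_ok, arr.ind = TRUE)
  resid <- ifelse(ok_direct[any_ok], d_direct[any_ok], d_shift[any_ok])
  pairs <- tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    product = (wa[idx[, 1]] / na_) * (wb[idx[, 2]] / nb_),
    shifted = !ok_direct[any_ok],
    resid = resid
  )
  list(pairs = pairs, wa = wa, wb = wb, na = na_, nb = nb_)
}

# Greedy one-to-one assignment: pairs taken in order of descending
# intensity product, ties broken by smaller m/z residual; each peak used
# at most once across the direct and shifted channels.
.greedy_assign <- function(pairs) {
  ord <- order(-pairs$product, pairs$resid, pairs$i, pairs$j)
  pairs <- pairs[ord, ]
  used_i <- logical(max(pairs$i)); used_j <- logical(max(pairs$j))
  take <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (!used_i[pairs$i[r]] && !used_j[pairs$j[r]]) {
      take[r] <- TRUE
      used_i[pairs$i[r]] <- TRUE
      used_j[pairs$j[r]] <- TRUE
    }
  }
  pairs[take, ]
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Computes the precursor-shift-aware cosine similarity: peak pairs are
#' eligible either directly (`|mz_a - mz_b| <= frag_tol`) or shifted by the
#' precursor mass difference (`|mz_b - mz_a - offset| <= frag_tol`). A
#' one-to-one assignment is chosen greedily by descending product of
#' square-root-scaled, norm-scaled intensities (ties broken by smaller m/z
#' residual), and the score is the sum of the matched products over the
#' product of the peak-vector norms, so identical spectra score 1.
#'
#' @param a,b Spectra: one-row spectra tibbles or lists with
#'   `precursor_mz` and `peaks`.
#' @param frag_tol Fragment m/z tolerance, Da (> 0).
#' @param scaling Intensity scaling before normalization: `"sqrt"`
#'   (default, the spectral-networking convention) or `"none"`.
#' @return One-row tibble: `query_id`, `target_id`, `score`,
#'   `matched_peaks`, `shifted_pairs`, `mass_offset` (target minus query
#'   precursor).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02,
                            scaling = c("sqrt", "none")) {
  scaling <- match.arg(scaling)
  if (!is.numeric(frag_tol) || frag_tol <= 0) {
    stop("`frag_tol` must be > 0", call. = FALSE)
  }
  a <- .as_spec(a); b <- .as_spec(b)
  shift <- b$precursor_mz - a$precursor_mz
  res <- tibble::tibble(
    query_id = as.character(a$spectrum_id),
    target_id = as.character(b$spectrum_id),
    score = 0, matched_peaks = 0L, shifted_pairs = 0L,
    mass_offset = shift
  )
  el <- .eligible_pairs(a$peaks, b$peaks, shift, frag_tol, scaling)
  if (is.null(el$pairs)) return(res)
  kept <- .greedy_assign(el$pairs)
  res$score <- min(1, sum(kept$product))
  res$matched_peaks <- nrow(kept)
  res$shifted_pairs <- sum(kept$shifted)
  res
}

#' Analog search of a query spectrum against a spectrum corpus
#'
#' Scores the query against every corpus spectrum whose precursor lies
#' within `±precursor_window` Da and returns the hits passing the score and
#' matched-peak thresholds, sorted by descending score (ties by smaller
#' absolute mass offset, then target id).
#'
#' @param query A spectrum (one-row spectra tibble or list).
#' @param corpus A spectra tibble (non-empty).
#' @param precursor_window Precursor search window, Da, below and above the
#'   query precursor.
#' @param min_score Minimum modified cosine score.
#' @param min_peaks Minimum matched-ion count.
#' @param frag_tol Fragment m/z tolerance, Da.
#' @param scaling Intensity scaling passed to [modified_cosine()].
#' @return Tibble of match results (possibly empty).
#' @export
analog_search <- function(query, corpus, precursor_window = 200,
                          min_score = 0.8, min_peaks = 6L, frag_tol = 0.02,
                          scaling = "sqrt") {
  corpus <- validate_spectra(corpus)
  if (!nrow(corpus)) stop("`corpus` must be non-empty", call. = FALSE)
  q <- .as_spec(query)
  cand <- corpus[abs(corpus$precursor_mz - q$precursor_mz) <=
                   precursor_window, ]
  if (!nrow(cand)) return(.empty_match())
  hits <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    modified_cosine(q, cand[i, ], frag_tol = frag_tol, scaling = scaling)
  })
  hits <- hits[hits$score >= min_score & hits$matched_peaks >= min_peaks, ]
  hits[order(-hits$score, abs(hits$mass_offset), hits$target_id), ]
}

.empty_match <- function() {
  tibble::tibble(query_id = character(), target_id = character(),
                 score = numeric(), matched_peaks = integer(),
                 shifted_pairs = integer(), mass_offset = numeric())
}

#' Two-tier library search of dataset spectra against a drug library
#'
#' Stage one collects candidate annotations at permissive search thresholds
#' (direct matches only: `|precursor difference| <= precursor_tol`). Stage
#' two applies the stricter acceptance thresholds; each dataset spectrum
#' keeps its best-scoring accepted library entry (ties broken by more
#' matched peaks, then entry id). Both tiers are reported.
#'
#' @param dataset A spectra tibble of query MS/MS spectra.
#' @param library A drug library tibble (non-empty).
#' @param precursor_tol,frag_tol Precursor / fragment m/z tolerances, Da.
#' @param search_min_score,search_min_peaks Stage-one thresholds.
#' @param accept_min_score,accept_min_peaks Stage-two thresholds.
#' @param preprocess Apply [preprocess_spectra()] to the dataset first.
#' @return Tibble with one row per (spectrum, entry) candidate:
#'   match statistics plus `accepted` and `is_best` flags and the entry's
#'   compound/parent names.
#' @export
library_search <- function(dataset, library, precursor_tol = 0.02,
                           frag_tol = 0.02, search_min_score = 0.7,
                           search_min_peaks = 2L, accept_min_score = 0.9,
                           accept_min_peaks = 5L, preprocess = FALSE) {
  library <- validate_drug_library(library)
  if (!nrow(library)) stop("`library` must be non-empty", call. = FALSE)
  dataset <- validate_spectra(dataset)
  if (preprocess) dataset <- preprocess_spectra(dataset)
  lib_prec <- library$precursor_mz
  res <- purrr::map_dfr(seq_len(nrow(dataset)), function(i) {
    q <- list(spectrum_id = dataset$spectrum_id[i],
              precursor_mz = dataset$precursor_mz[i],
              peaks = dataset$peaks[[i]])
    cand <- which(abs(lib_prec - q$precursor_mz) <= precursor_tol)
    if (!length(cand)) return(NULL)
    hits <- purrr::map_dfr(cand, function(j) {
      r <- modified_cosine(q, list(spectrum_id = library$entry_id[j],
                                   precursor_mz = library$precursor_mz[j],
                                   peaks = library$peaks[[j]]),
                           frag_tol = frag_tol)
      r$compound_name <- library$compound_name[j]
      r$parent_drug <- library$parent_drug[j]
      r$annotation_type <- library$annotation_type[j]
      r
    })
    hits <- hits[hits$score >= search_min_score &
                   hits$matched_peaks >= search_min_peaks, ]
    if (!nrow(hits)) return(NULL)
    hits$accepted <- hits$score >= accept_min_score &
      hits$matched_peaks >= accept_min_peaks
    hits$is_best <- FALSE
    acc <- which(hits$accepted)
    if (length(acc)) {
      best <- acc[order(-hits$score[acc], -hits$matched_peaks[acc],
                        hits$target_id[acc])][1]
      hits$is_best[best] <- TRUE
    }
    hits
  })
  if (!nrow(res)) {
    res <- .empty_match()
    res$compound_name <- character()
    res$parent_drug <- character()
    res$annotation_type <- character()
    res$accepted <- logical()
    res$is_best <- logical()
  }
  dplyr::rename(res, spectrum_id = "query_id", entry_id = "target_id")
}
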