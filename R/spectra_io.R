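# Spectrum model and I/O: MGF read/write, USI parsing, feature/quant tables,
# and extracted ion chromatograms from MS1 scans.
#
# Spectra are represented as a tibble with one row per spectrum:
#   spectrum_id, precursor_mz, rt (minutes), ms_level, source_file,
#   peaks (list-column of tibbles with mz, intensity).

#' Construct a spectra tibble
#'
#' @param spectrum_id Character vector of unique spectrum identifiers
#'   (USI or `file::scan`).
#' @param precursor_mz Precursor m/z per spectrum (required for MS2).
#' @param peaks List of data frames with columns `mz`, `intensity`;
#'   peaks are sorted by m/z on construction.
#' @param rt Retention time in minutes (optional, `NA` allowed).
#' @param ms_level MS level, 1 or 2 (default 2).
#' @param source_file Originating file name (optional).
#' @return A validated spectra tibble.
#' @export
#' @examples
#' spectra_tbl("s1", 346.122, list(data.frame(mz = c(100, 200), intensity = c(5, 10))))
spectra_tbl <- function(spectrum_id, precursor_mz, peaks, rt = NA_real_,
                        ms_level = 2L, source_file = NA_character_) {
  x <- tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    rt = as.numeric(rt),
    ms_level = as.integer(ms_level),
    source_file = as.character(source_file),
    peaks = purrr::map(peaks, function(p) {
      p <- tibble::as_tibble(p)[, c("mz", "intensity")]
      p[order(p$mz), ]
    })
  )
  validate_spectra(x)
}

#' Validate a spectra tibble
#'
#' Checks the spectrum invariants: peaks sorted ascending by m/z,
#' non-negative intensities, positive precursor m/z for MS2 scans, and
#' unique spectrum ids.
#'
#' @param x A spectra tibble.
#' @return `x`, invisibly usable in pipes.
#' @export
validate_spectra <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("spectrum_id", "precursor_mz", "ms_level", "peaks")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("spectra tibble missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$spectrum_id)) {
    stop("duplicate spectrum_id values", call. = FALSE)
  }
  ok <- purrr::map_lgl(x$peaks, function(p) {
    !is.unsorted(p$mz) && all(p$intensity >= 0)
  })
  if (!all(ok)) {
    stop("peaks must be sorted ascending by m/z with intensities >= 0 (",
         paste(x$spectrum_id[!ok], collapse = ", "), ")", call. = FALSE)
  }
  bad <- x$ms_level == 2L & !(is.finite(x$precursor_mz) & x$precursor_mz > 0)
  if (any(bad)) {
    stop("MS2 spectra require precursor_mz > 0: ",
         paste(x$spectrum_id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read an MGF spectral file
#'
#' Parses a Mascot Generic Format file (BEGIN IONS/END IONS blocks with
#' `PEPMASS`, optional `TITLE`, `RTINSECONDS`, `SCANS`) into a spectra
#' tibble. The first `PEPMASS` value is taken as the precursor m/z and
#' `RTINSECONDS` is converted to minutes. When no `TITLE` is present the
#' spectrum id is synthesized as `"<file>::<scan>"`.
#'
#' @param path MGF file path.
#' @return A spectra tibble (empty for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  }
  if (!length(begin)) return(spectra_tbl(character(), numeric(), list()))
  base <- basename(path)
  out <- purrr::map(seq_along(begin), function(b) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- get("PEPMASS")
    if (is.na(pep)) {
      stop("MGF block ", b, " in ", base, " is missing PEPMASS",
           call. = FALSE)
    }
    precursor <- as.numeric(strsplit(pep, "[ \t]+")[[1]][1])
    if (is.na(precursor)) {
      stop("MGF block ", b, " in ", base, ": unparseable PEPMASS '", pep, "'",
           call. = FALSE)
    }
    rtsec <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    scan <- get("SCANS")
    id <- get("TITLE")
    if (is.na(id)) {
      id <- paste0(base, "::", if (is.na(scan)) as.character(b) else scan)
    }
    peak_lines <- block[!is_kv]
    if (length(peak_lines)) {
      m <- do.call(rbind, strsplit(peak_lines, "[ \t]+"))
      pk <- tibble::tibble(mz = as.numeric(m[, 1]),
                           intensity = as.numeric(m[, 2]))
      if (anyNA(pk$mz) || anyNA(pk$intensity)) {
        stop("MGF block ", b, " in ", base, ": unparseable peak line",
             call. = FALSE)
      }
    } else {
      pk <- tibble::tibble(mz = numeric(), intensity = numeric())
    }
    list(id = id, precursor = precursor,
         rt = if (is.na(rtsec)) NA_real_ else rtsec / 60, peaks = pk)
  })
  spectra_tbl(
    spectrum_id = purrr::map_chr(out, "id"),
    precursor_mz = purrr::map_dbl(out, "precursor"),
    peaks = purrr::map(out, "peaks"),
    rt = purrr::map_dbl(out, "rt"),
    ms_level = 2L,
    source_file = base
  )
}

#' Write a spectra tibble to MGF
#'
#' Writes canonical fields (`TITLE`, `PEPMASS`, `RTINSECONDS`, peak list)
#' with full double precision so that [read_mgf()] round-trips precursor,
#' peaks, and spectrum id exactly.
#'
#' @param x A spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  x <- validate_spectra(x)
  blocks <- purrr::pmap(
    list(x$spectrum_id, x$precursor_mz, x$rt, x$peaks),
    function(id, prec, rt, pk) {
      hdr <- c("BEGIN IONS",
               paste0("TITLE=", id),
               paste0("PEPMASS=", sprintf("%.17g", prec)))
      if (!is.na(rt)) {
        hdr <- c(hdr, paste0("RTINSECONDS=", sprintf("%.17g", rt * 60)))
      }
      c(hdr,
        sprintf("%.17g %.17g", pk$mz, pk$intensity),
        "END IONS", "")
    }
  )
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Parse a metabolomics universal spectrum identifier (USI)
#'
#' Splits a `mzspec:`-prefixed USI into its collection identifier, run
#' name, and scan reference (the index-type token and index, preserved
#' verbatim so the USI round-trips).
#'
#' @param usi USI string, e.g. `"mzspec:MSV000080673:run1:scan:123"`.
#' @return One-row tibble with `collection_id`, `run_name`, `scan_ref`.
#' @export
parse_usi <- function(usi) {
  if (!is.character(usi) || length(usi) != 1L) {
    stop("`usi` must be a single string", call. = FALSE)
  }
  parts <- strsplit(usi, ":", fixed = TRUE)[[1]]
  if (parts[1] != "mzspec" || length(parts) < 5L) {
    stop("not a valid USI (expected 'mzspec:' prefix and >= 5 fields): ",
         usi, call. = FALSE)
  }
  tibble::tibble(
    collection_id = parts[2],
    run_name = parts[3],
    scan_ref = paste(parts[-(1:3)], collapse = ":")
  )
}

#' Reassemble a USI from its components
#'
#' @param parsed One-row tibble as returned by [parse_usi()].
#' @return USI string.
#' @export
build_usi <- function(parsed) {
  paste("mzspec", parsed$collection_id, parsed$run_name, parsed$scan_ref,
        sep = ":")
}

# ---- feature tables --------------------------------------------------------

#' Construct a feature table
#'
#' A feature table bundles the per-feature descriptors (m/z, retention
#' time, MS2 spectrum link), the features x samples peak-area matrix, and
#' the per-sample metadata, mirroring the quantification tables exported by
#' feature-finding tools.
#'
#' @param features Tibble with `feature_id`, `mz`, `rt`, and optional
#'   `ms2_spectrum_id`.
#' @param areas Tibble with `feature_id` plus one numeric column per sample
#'   (peak areas, >= 0).
#' @param samples Tibble with `sample_id`, logical `is_blank`, and optional
#'   `group`, `age`, `sex`.
#' @param detected Optional logical tibble shaped like `areas`; defaults to
#'   `area > 0`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, areas, samples, detected = NULL) {
  features <- tibble::as_tibble(features)
  areas <- tibble::as_tibble(areas)
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id values", call. = FALSE)
  }
  sample_cols <- setdiff(names(areas), "feature_id")
  if (!setequal(areas$feature_id, features$feature_id)) {
    stop("areas and features must describe the same feature_ids",
         call. = FALSE)
  }
  missing_meta <- setdiff(sample_cols, samples$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  a <- as.matrix(areas[, sample_cols])
  if (any(a < 0, na.rm = TRUE)) {
    stop("negative peak areas are not allowed", call. = FALSE)
  }
  areas <- areas[match(features$feature_id, areas$feature_id), ]
  if (is.null(detected)) {
    detected <- areas
    detected[sample_cols] <- lapply(areas[sample_cols], function(v) v > 0)
  }
  if (!"is_blank" %in% names(samples)) samples$is_blank <- FALSE
  structure(
    list(features = features, areas = areas,
         detected = tibble::as_tibble(detected),
         samples = samples[match(c(sample_cols), samples$sample_id), ]),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      nrow(x$samples), " samples (", sum(x$samples$is_blank), " blanks)\n",
      sep = "")
  invisible(x)
}

#' Sample ids of a feature table
#' @param ft A `feature_table`.
#' @return Character vector of sample ids (column order of the area matrix).
#' @export
ft_samples <- function(ft) ft$samples$sample_id

#' Tidy a feature table into long format
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Long tibble with `feature_id`, `sample_id`, `area`, `detected`.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  long_a <- tidyr::pivot_longer(x$areas, -"feature_id",
                                names_to = "sample_id", values_to = "area")
  long_d <- tidyr::pivot_longer(x$detected, -"feature_id",
                                names_to = "sample_id", values_to = "detected")
  dplyr::left_join(long_a, long_d, by = c("feature_id", "sample_id"))
}

#' Read a feature quantification table and sample metadata
#'
#' @param csv_path Wide CSV, one row per feature: `feature_id`, `mz`, `rt`,
#'   optional `ms2_spectrum_id`, then one column of peak areas per sample.
#' @param metadata_path CSV keyed by `sample_id` with at least `is_blank`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(csv_path, metadata_path) {
  x <- readr::read_csv(csv_path, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("sample metadata must have a sample_id column", call. = FALSE)
  }
  if ("is_blank" %in% names(meta)) meta$is_blank <- as.logical(meta$is_blank)
  desc_cols <- intersect(c("feature_id", "mz", "rt", "ms2_spectrum_id"),
                         names(x))
  if (!all(c("feature_id", "mz", "rt") %in% desc_cols)) {
    stop("feature table must have feature_id, mz, rt columns", call. = FALSE)
  }
  x$feature_id <- as.character(x$feature_id)
  feature_table(
    features = x[, desc_cols],
    areas = x[, c("feature_id", setdiff(names(x), desc_cols))],
    samples = meta
  )
}

#' Write a feature table to CSV files
#'
#' @param ft A [feature_table()].
#' @param csv_path,metadata_path Output paths for the wide quantification
#'   table and the sample metadata.
#' @return `csv_path`, invisibly.
#' @export
write_feature_table <- function(ft, csv_path, metadata_path) {
  wide <- dplyr::left_join(ft$features, ft$areas, by = "feature_id")
  readr::write_csv(wide, csv_path)
  readr::write_csv(ft$samples, metadata_path)
  invisible(csv_path)
}

# ---- extracted ion chromatograms ------------------------------------------

#' Extracted ion chromatograms from an MS1 scan table
#'
#' For each target m/z, sums the intensity of all signals within `±tol`
#' per MS1 scan, in acquisition order.
#'
#' @param scans Tibble of MS1 signals with columns `scan_index`, `rt`,
#'   `mz`, `intensity` (one row per signal).
#' @param targets Numeric vector of target m/z values.
#' @param tol Absolute m/z tolerance (> 0).
#' @return Tibble with `target_mz`, `scan_index`, `rt`, `intensity`;
#'   one row per target per scan (zeros where no signal matched).
#' @export
xic_traces <- function(scans, targets, tol) {
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop("`tol` must be a single positive number", call. = FALSE)
  }
  scans <- tibble::as_tibble(scans)
  grid <- dplyr::distinct(scans[, c("scan_index", "rt")])
  grid <- grid[order(grid$scan_index), ]
  purrr::map_dfr(targets, function(tm) {
    hit <- scans[abs(scans$mz - tm) <= tol, ]
    agg <- dplyr::summarise(dplyr::group_by(hit, .data$scan_index),
                            intensity = sum(.data$intensity), .groups = "drop")
    out <- dplyr::left_join(grid, agg, by = "scan_index")
    out$intensity[is.na(out$intensity)] <- 0
    dplyr::bind_cols(tibble::tibble(target_mz = tm), out)
  })
}

#' Extracted ion chromatograms from an mzML file
#'
#' Reads the MS1 scans of an mzML file (via the Bioconductor \pkg{mzR}
#' parser) and computes per-target XIC traces with [xic_traces()].
#' Intensities within `±tol` of each target are summed per scan.
#'
#' @param path mzML file with MS1 scans in retention-time order.
#' @param targets Numeric vector of target m/z values.
#' @param tol Absolute m/z tolerance (> 0).
#' @return Tibble as for [xic_traces()]; empty (with a warning) when the
#'   file contains no MS1 scans.
#' @export
read_mzml_ms1_traces <- function(path, targets, tol) {
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop("`tol` must be a single positive number", call. = FALSE)
  }
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) {
    warning("no MS1 scans in ", path)
    return(tibble::tibble(target_mz = numeric(), scan_index = integer(),
                          rt = numeric(), intensity = numeric()))
  }
  scans <- purrr::map_dfr(ms1, function(i) {
    pk <- mzR::peaks(fh, i)
    tibble::tibble(scan_index = i, rt = hd$retentionTime[i] / 60,
                   mz = pk[, 1], intensity = pk[, 2])
  })
  xic_traces(scans, targets, tol)
}
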