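#' Build peak records in code
#'
#' Constructor for the per-residue oxidized/reduced peak-intensity records
#' that [compute_pre_profile()] consumes. Records with a non-positive reduced
#' intensity (no computable ratio) or a negative oxidized intensity are kept
#' but flagged invalid.
#'
#' @param residue Integer residue numbers.
#' @param intensity_ox Peak intensities of the oxidized (paramagnetic)
#'   sample, arbitrary units.
#' @param intensity_red Peak intensities of the reduced (diamagnetic)
#'   sample, arbitrary units.
#' @param replicate Replicate identifiers (default all 1).
#' @param label Assignment labels, e.g. `"bb"` for a backbone NH or
#'   `"W404sc"` for a side-chain peak (default `"bb"`).
#' @return A data frame of class `peak_records` with a logical `valid`
#'   column.
#' @examples
#' peak_records(1:3, c(50, 80, 95), c(100, 100, 100))
#' @export
peak_records <- function(residue, intensity_ox, intensity_red,
                         replicate = 1L, label = "bb") {
  n <- length(residue)
  df <- data.frame(
    residue = as.integer(residue),
    label = rep_len(as.character(label), n),
    intensity_ox = as.numeric(intensity_ox),
    intensity_red = as.numeric(intensity_red),
    replicate = rep_len(as.integer(replicate), n),
    stringsAsFactors = FALSE
  )
  key <- paste(df$residue, df$label, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, label, replicate) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  df$valid <- is.finite(df$intensity_ox) & is.finite(df$intensity_red) &
    df$intensity_ox >= 0 & df$intensity_red > 0
  class(df) <- c("peak_records", "data.frame")
  df
}

#' Read an oxidized/reduced peak-intensity table
#'
#' Reads a delimited text file with header columns `residue`,
#' `intensity_ox`, `intensity_red` and optionally `label` and `replicate`
#' (missing `replicate` is taken as 1, missing `label` as `"bb"`). Rows with
#' non-numeric intensities are reported with their line numbers.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default: by extension, TSV otherwise), `"tsv"`
#'   or `"csv"`.
#' @return A `peak_records` data frame; see [peak_records()].
#' @export
read_peak_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak table not found: ", path)
  sep <- switch(dialect,
                tsv = "\t", csv = ",",
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
                       else "\t")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("residue", "intensity_ox", "intensity_red")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peak table '", path, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$intensity_ox))) |
               !is.finite(suppressWarnings(as.numeric(df$intensity_red))))
  if (length(bad)) {
    warning("non-numeric intensities on data line(s) ",
            paste(bad, collapse = ", "), " of ", path,
            "; flagged invalid")
    df$intensity_ox <- suppressWarnings(as.numeric(df$intensity_ox))
    df$intensity_red <- suppressWarnings(as.numeric(df$intensity_red))
    df$intensity_ox[is.na(df$intensity_ox)] <- -1
    df$intensity_red[is.na(df$intensity_red)] <- -1
  }
  peak_records(df$residue, df$intensity_ox, df$intensity_red,
               replicate = if ("replicate" %in% names(df)) df$replicate else 1L,
               label = if ("label" %in% names(df)) df$label else "bb")
}

#' Write peak records in the package's TSV dialect
#'
#' @param records A `peak_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(records, path) {
  cols <- c("residue", "label", "intensity_ox", "intensity_red", "replicate")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default intensity-ratio classification bins
#'
#' Half-open bins `[lo, hi)`, exhaustive over `[0, Inf)`: strong `< 0.4`,
#' intermediate `[0.4, 0.6)`, moderate `[0.6, 0.8)`, baseline `[0.8, 1.2)`
#' and elevated `>= 1.2`. Most ratios in a weak-binding experiment fall in
#' the baseline band around 1; ratios above it reflect intensity noise.
#'
#' @return A list with numeric `breaks` and character `labels`
#'   (`length(labels) == length(breaks) - 1`).
#' @export
default_pre_bins <- function() {
  list(breaks = c(0, 0.4, 0.6, 0.8, 1.2, Inf),
       labels = c("strong", "intermediate", "moderate", "baseline",
                  "elevated"))
}

classify_pre <- function(x, bins = default_pre_bins()) {
  as.character(cut(x, breaks = bins$breaks, labels = bins$labels,
                   right = FALSE, include.lowest = TRUE))
}

label_region <- function(residue, regions) {
  out <- rep("none", length(residue))
  for (nm in names(regions)) out[residue %in% regions[[nm]]] <- nm
  out
}

#' PRE profile with replicate statistics and classification
#'
#' For each residue/label pair, the PRE of every replicate is the oxidized
#' over reduced intensity ratio; the profile reports the replicate mean, the
#' sample (n-1) standard deviation, the replicate count, a class label from
#' the configured bins and a region annotation from the configured residue
#' sets. Invalid records are excluded from the statistics but counted in
#' `attr(, "n_invalid")`.
#'
#' @param records A `peak_records` data frame.
#' @param bins Classification bins, see [default_pre_bins()].
#' @param regions Named list of integer residue vectors (e.g.
#'   `list(primary = ..., polybasic = ..., tripartite = ...)`); residues in
#'   none of them are annotated `"none"`.
#' @return A data frame of class `pre_profile` with columns `residue`,
#'   `label`, `pre_mean`, `pre_sd`, `n_replicates`, `class_label`,
#'   `region_label`.
#' @examples
#' rec <- peak_records(rep(1:2, 2), c(80, 30, 90, 32), rep(100, 4),
#'                     replicate = rep(1:2, each = 2))
#' compute_pre_profile(rec)
#' @export
compute_pre_profile <- function(records, bins = default_pre_bins(),
                                regions = list()) {
  valid <- records[records$valid, , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid peak records")
  valid$pre <- valid$intensity_ox / valid$intensity_red
  sp <- split(valid, paste(valid$residue, valid$label, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(
      residue = g$residue[1],
      label = g$label[1],
      pre_mean = mean(g$pre),
      pre_sd = if (nrow(g) > 1L) stats::sd(g$pre) else 0,
      n_replicates = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$residue, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out$class_label <- classify_pre(out$pre_mean, bins)
  out$region_label <- label_region(out$residue, regions)
  class(out) <- c("pre_profile", "data.frame")
  attr(out, "n_invalid") <- sum(!records$valid)
  out
}

#' PRE profile from summed replicate spectra
#'
#' Alternative replicate handling for low-sensitivity samples: intensities
#' are summed across replicates before taking the ratio, i.e.
#' `pre = sum(I_ox) / sum(I_red)` per residue. Equals the mean-of-ratios
#' profile exactly when all replicate reduced intensities of a residue are
#' equal; no standard deviation is defined.
#'
#' @inheritParams compute_pre_profile
#' @return A `pre_profile` data frame with `pre_sd = NA` and
#'   `n_replicates` the number of summed replicates.
#' @export
summed_replicate_profile <- function(records, bins = default_pre_bins(),
                                     regions = list()) {
  valid <- records[records$valid, , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid peak records")
  sp <- split(valid, paste(valid$residue, valid$label, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(
      residue = g$residue[1],
      label = g$label[1],
      pre_mean = sum(g$intensity_ox) / sum(g$intensity_red),
      pre_sd = NA_real_,
      n_replicates = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$residue, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out$class_label <- classify_pre(out$pre_mean, bins)
  out$region_label <- label_region(out$residue, regions)
  class(out) <- c("pre_profile", "data.frame")
  out
}

#' Normalized intensity-ratio perturbation analysis
#'
#' Compares peak intensities of the free protein with intensities measured
#' at the same cross-peak positions in the presence of a binding partner.
#' Because the two samples differ in concentration, raw ratios
#' `I_complex / I_free` are normalized by their mean over all shared
#' residues; residues whose normalized ratio falls below the threshold are
#' reported as perturbed (exchange broadening or cross-peak shifts). The
#' analysis is invariant to global rescaling of either spectrum.
#'
#' @param free_peaks Data frame with columns `residue` and `intensity`
#'   for the free-protein spectrum.
#' @param complex_peaks Data frame with the same columns for the
#'   partner-containing sample, measured at the free-protein peak positions.
#' @param threshold Normalized-ratio cutoff below which a residue counts as
#'   perturbed (default 0.75).
#' @return A list with `table` (data frame: `residue`, `ratio`,
#'   `normalized`, `perturbed`) and `perturbed` (sorted residue numbers).
#' @examples
#' free <- data.frame(residue = 1:4, intensity = c(100, 100, 100, 100))
#' cplx <- data.frame(residue = 1:4, intensity = c(100, 100, 50, 150))
#' normalized_ratio_perturbation(free, cplx)$perturbed   # residue 3
#' @export
normalized_ratio_perturbation <- function(free_peaks, complex_peaks,
                                          threshold = 0.75) {
  for (df in list(free_peaks, complex_peaks)) {
    if (!all(c("residue", "intensity") %in% names(df))) {
      stop("peak inputs need columns 'residue' and 'intensity'")
    }
  }
  shared <- intersect(free_peaks$residue, complex_peaks$residue)
  if (length(shared) == 0L) {
    stop("no residues shared between free and complex peak tables")
  }
  f <- free_peaks$intensity[match(shared, free_peaks$residue)]
  c_ <- complex_peaks$intensity[match(shared, complex_peaks$residue)]
  ratio <- c_ / f
  normalized <- ratio / mean(ratio)
  tab <- data.frame(residue = shared, ratio = ratio,
                    normalized = normalized,
                    perturbed = normalized < threshold)
  tab <- tab[order(tab$residue), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, perturbed = sort(shared[normalized < threshold]))
}

#' Export a PRE profile
#'
#' @param profile A `pre_profile` data frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_pre_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(profile, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(profile, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}
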