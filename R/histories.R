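#' Photon history table
#'
#' Per-detected-photon record of the partial pathlength `L` (cm) and the
#' dimensionless accumulated momentum transfer `Y = sum(1 - cos(theta))` in
#' each tissue category, as produced by a dynamic light scattering Monte Carlo.
#' This is the substrate for the history-based field autocorrelation
#' [g1_from_histories()].
#'
#' @param detector_id Integer vector, one entry per detected photon.
#' @param L Numeric matrix (photons x tissues) of partial pathlengths (cm).
#' @param Y Numeric matrix (photons x tissues) of momentum transfer.
#' @param tissue_labels Character vector naming the tissue columns.
#' @param n_launched Number of photons launched in the simulation.
#' @param wavelength_nm Vacuum wavelength (nm).
#' @param detectors Data frame with columns `id`, `sds_mm`, `radius_mm`, `na`
#'   declaring each detector.
#' @param source Character tag recording how the table was generated.
#' @return An object of class `photon_history_table`.
#' @export
photon_history_table <- function(detector_id, L, Y, tissue_labels, n_launched,
                                 wavelength_nm, detectors,
                                 source = "unspecified") {
  L <- as.matrix(L); Y <- as.matrix(Y)
  nt <- length(tissue_labels)
  if (ncol(L) != nt || ncol(Y) != nt) {
    stop("number of L and Y columns must equal the number of tissue labels")
  }
  if (nrow(L) != length(detector_id) || nrow(Y) != length(detector_id)) {
    stop("detector_id, L and Y must agree on the number of photons")
  }
  if (any(L < 0)) stop("all partial pathlengths must be >= 0")
  if (any(Y < 0)) stop("all momentum transfer values must be >= 0")
  if (!is.finite(n_launched) || n_launched < length(detector_id)) {
    stop("n_launched must be >= the number of detected photons")
  }
  req <- c("id", "sds_mm", "radius_mm", "na")
  if (!all(req %in% names(detectors))) {
    stop("detectors must have columns id, sds_mm, radius_mm, na")
  }
  if (!all(detector_id %in% detectors$id)) {
    stop("every detector_id must reference a declared detector")
  }
  colnames(L) <- tissue_labels
  colnames(Y) <- tissue_labels
  structure(
    list(
      detector_id = as.integer(detector_id), L = L, Y = Y,
      tissue_labels = tissue_labels, n_launched = as.numeric(n_launched),
      wavelength_nm = wavelength_nm, detectors = detectors, source = source
    ),
    class = "photon_history_table"
  )
}

#' @export
print.photon_history_table <- function(x, ...) {
  cat(sprintf(
    "Photon history table: %d detected / %.3g launched, %d tissues (%s),\n  %d detectors, %g nm [%s]\n",
    length(x$detector_id), x$n_launched, length(x$tissue_labels),
    paste(x$tissue_labels, collapse = ", "), nrow(x$detectors),
    x$wavelength_nm, x$source
  ))
  invisible(x)
}

#' History-based field autocorrelation
#'
#' Discrete pathlength-resolved field autocorrelation: each detected photon
#' contributes
#' `exp(-(1/3) * sum_i k_i^2 * Y_i * 6 * BFi_i * tau) * exp(-sum_i mu_a_i * L_i)`
#' where `k_i = 2 pi n_i / lambda` is the in-medium wavenumber of tissue `i`.
#' The returned curve is normalized so that g1(0) = 1 exactly.
#'
#' @param histories A [photon_history_table()].
#' @param optics_by_tissue Named list of [optical_properties()], one per
#'   tissue label in the table.
#' @param flow A [flow_state()] with a BFi for every tissue label.
#' @param tau Delay grid (s).
#' @param detector_id Which detector's photons to use.
#' @return A [correlation_curve()] of kind `field_g1`.
#' @export
g1_from_histories <- function(histories, optics_by_tissue, flow, tau,
                              detector_id) {
  stopifnot(inherits(histories, "photon_history_table"),
            inherits(flow, "flow_state"))
  labels <- histories$tissue_labels
  if (!all(labels %in% names(optics_by_tissue))) {
    stop("optics_by_tissue is missing labels: ",
         paste(setdiff(labels, names(optics_by_tissue)), collapse = ", "))
  }
  if (!all(labels %in% names(flow$bfi_by_tissue))) {
    stop("flow state is missing labels: ",
         paste(setdiff(labels, names(flow$bfi_by_tissue)), collapse = ", "))
  }
  sel <- histories$detector_id == detector_id
  if (!any(sel)) stop("no detected photons for detector ", detector_id)
  L <- histories$L[sel, , drop = FALSE]
  Y <- histories$Y[sel, , drop = FALSE]
  lam_cm <- histories$wavelength_nm * 1e-7
  k2 <- vapply(labels, function(tl) {
    (2 * pi * optics_by_tissue[[tl]]$refractive_index / lam_cm)^2
  }, numeric(1))
  mua <- vapply(labels, function(tl) optics_by_tissue[[tl]]$mu_a, numeric(1))
  bfi <- flow$bfi_by_tissue[labels]
  # decay rate per photon: (1/3) * sum_i k_i^2 Y_i * 6 BFi_i = 2 sum_i k_i^2 Y_i BFi_i
  a <- drop(Y %*% (2 * k2 * bfi))
  w <- exp(-drop(L %*% mua))
  w_sum <- sum(w)
  vals <- vapply(tau, function(t) sum(w * exp(-a * t)) / w_sum, numeric(1))
  correlation_curve(tau, vals, "field_g1")
}

#' Write / read a photon history table as tab-separated text
#'
#' The text format is the interchange contract between the Monte Carlo
#' generator and the forward models: a '#'-prefixed metadata header
#' (`n_launched`, `wavelength_nm`, `tissue_labels`, `source`, one `detector`
#' line per detector) followed by a header row and columns `detector_id`,
#' `L_<tissue>_cm` (one per tissue), `Y_<tissue>` (one per tissue).
#'
#' @param table A [photon_history_table()].
#' @param path Output file path.
#' @return `write_history_table` returns `path` invisibly;
#'   `read_history_table` returns the parsed [photon_history_table()].
#' @export
write_history_table <- function(table, path) {
  stopifnot(inherits(table, "photon_history_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_launched\t%.17g", table$n_launched), con)
  writeLines(sprintf("# wavelength_nm\t%.17g", table$wavelength_nm), con)
  writeLines(sprintf("# tissue_labels\t%s",
                     paste(table$tissue_labels, collapse = "\t")), con)
  writeLines(sprintf("# source\t%s", table$source), con)
  for (i in seq_len(nrow(table$detectors))) {
    d <- table$detectors[i, ]
    writeLines(sprintf("# detector\t%d\t%.17g\t%.17g\t%.17g",
                       d$id, d$sds_mm, d$radius_mm, d$na), con)
  }
  df <- data.frame(detector_id = table$detector_id)
  for (j in seq_along(table$tissue_labels)) {
    df[[paste0("L_", table$tissue_labels[j], "_cm")]] <- table$L[, j]
  }
  for (j in seq_along(table$tissue_labels)) {
    df[[paste0("Y_", table$tissue_labels[j])]] <- table$Y[, j]
  }
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_table
#' @export
read_history_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- strsplit(sub("^#\\s*", "", hdr), "\t")
  get1 <- function(key) {
    m <- Filter(function(x) x[1] == key, meta)
    if (length(m) == 0) stop("history file missing metadata key: ", key)
    m[[1]][-1]
  }
  n_launched <- as.numeric(get1("n_launched"))
  wavelength_nm <- as.numeric(get1("wavelength_nm"))
  tissue_labels <- get1("tissue_labels")
  source <- get1("source")
  det_rows <- Filter(function(x) x[1] == "detector", meta)
  if (length(det_rows) == 0) stop("history file declares no detectors")
  detectors <- do.call(rbind, lapply(det_rows, function(x) {
    data.frame(id = as.integer(x[2]), sds_mm = as.numeric(x[3]),
               radius_mm = as.numeric(x[4]), na = as.numeric(x[5]))
  }))
  body <- utils::read.table(textConnection(lines[!startsWith(lines, "#")]),
                            header = TRUE, sep = "\t")
  l_cols <- paste0("L_", tissue_labels, "_cm")
  y_cols <- paste0("Y_", tissue_labels)
  missing_cols <- setdiff(c("detector_id", l_cols, y_cols), names(body))
  if (length(missing_cols) > 0) {
    stop("history file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  L <- as.matrix(body[, l_cols, drop = FALSE])
  Y <- as.matrix(body[, y_cols, drop = FALSE])
  bad <- which(rowSums(L < 0) + rowSums(Y < 0) > 0)
  if (length(bad) > 0) {
    stop("negative pathlength or momentum transfer at data row ", bad[1])
  }
  photon_history_table(body$detector_id, L, Y, tissue_labels, n_launched,
                       wavelength_nm, detectors, source = source)
}
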