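#' Layered slab geometry for the Monte Carlo
#'
#' Planar layered medium: ordered layers from the surface down, the last layer
#' semi-infinite, plus a set of annular surface detectors centred on a pencil
#' source at the origin.
#'
#' @param layers Data frame with columns `tissue` (label) and `thickness_mm`
#'   (> 0; the last layer's thickness is ignored and treated as semi-infinite).
#' @param detectors Data frame with columns `id`, `sds_mm` (> 0), `radius_mm`
#'   (annulus half-width, > 0) and `na` (numerical aperture in air, in (0, 1]).
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(layers, detectors) {
  stopifnot(all(c("tissue", "thickness_mm") %in% names(layers)),
            all(c("id", "sds_mm", "radius_mm", "na") %in% names(detectors)))
  if (any(layers$thickness_mm <= 0)) stop("layer thicknesses must be > 0")
  if (any(detectors$sds_mm <= 0)) stop("detector SDS must be > 0")
  if (any(detectors$na <= 0 | detectors$na > 1)) stop("detector NA must be in (0, 1]")
  if (anyDuplicated(detectors$id)) stop("detector ids must be unique")
  structure(list(layers = layers, detectors = detectors), class = "slab_geometry")
}

#' Four-layer head slab presets
#'
#' Scalp / skull / CSF / brain slabs whose scalp-to-brain depth matches the
#' probed anatomical positions: scalp 5 mm, skull sized so the extracerebral
#' thickness (scalp + skull + CSF) equals `depth_mm`, CSF 2 mm, brain
#' semi-infinite.
#'
#' @param depth_mm Extracerebral thickness: 10, 15 or 20 mm (others allowed).
#' @param sds_mm Detector separations (mm).
#' @param radius_mm Annulus half-width per detector (mm).
#' @param na Detector numerical aperture (1 accepts every escaping photon).
#' @return A [slab_geometry()].
#' @export
slab_head_model <- function(depth_mm = 15, sds_mm = seq(5, 40, by = 5),
                            radius_mm = 1, na = 1) {
  skull <- depth_mm - 5 - 2
  if (skull <= 0) stop("depth_mm too small for the scalp/skull/CSF stack")
  layers <- data.frame(
    tissue = c("scalp", "skull", "csf", "brain"),
    thickness_mm = c(5, skull, 2, Inf),
    stringsAsFactors = FALSE
  )
  detectors <- data.frame(
    id = seq_along(sds_mm), sds_mm = sds_mm,
    radius_mm = radius_mm, na = na
  )
  slab_geometry(layers, detectors)
}

#' Run the layered-slab dynamic light scattering Monte Carlo
#'
#' Isotropic-scattering transport at the reduced scattering coefficient
#' (similarity relation). Absorption is recorded analytically through the
#' per-layer partial pathlengths; per-layer dimensionless momentum transfer
#' `Y = sum(1 - cos theta)` is accumulated at each scattering event. Photons
#' exiting the top surface within a detector annulus and acceptance angle are
#' recorded in a [photon_history_table()].
#'
#' @param geometry A [slab_geometry()].
#' @param optics_by_tissue Named list of [optical_properties()] covering every
#'   layer label.
#' @param n_photons Photons to launch (>= 1e4 for meaningful statistics).
#' @param seed Integer RNG seed.
#' @param wavelength_nm Recorded in the history table metadata.
#' @param weight_cutoff Photons are terminated when their potential absorption
#'   weight `exp(-sum mu_a L)` falls below this value.
#' @param fresnel_surface Apply Fresnel reflection at the tissue-air surface.
#' @return An object of class `mc_run_result`: fields `histories`
#'   ([photon_history_table()]), `reflectance` (data frame with per-detector
#'   detected weight fraction and per-area reflectance, 1/mm^2), and
#'   `accounting` (exit / terminated photon fractions).
#' @export
run_layered_mc <- function(geometry, optics_by_tissue, n_photons, seed,
                           wavelength_nm = 850, weight_cutoff = 1e-7,
                           fresnel_surface = TRUE) {
  stopifnot(inherits(geometry, "slab_geometry"))
  if (n_photons < 1e4) stop("n_photons must be >= 1e4")
  labels <- geometry$layers$tissue
  missing <- setdiff(labels, names(optics_by_tissue))
  if (length(missing) > 0) {
    stop("optics_by_tissue missing labels: ", paste(missing, collapse = ", "))
  }
  mu_a <- vapply(labels, function(l) optics_by_tissue[[l]]$mu_a, numeric(1))
  mu_sp <- vapply(labels, function(l) optics_by_tissue[[l]]$mu_s_prime, numeric(1))
  n_med <- optics_by_tissue[[labels[1]]]$refractive_index
  det <- geometry$detectors
  r_lo <- pmax(0, (det$sds_mm - det$radius_mm) / 10)
  r_hi <- (det$sds_mm + det$radius_mm) / 10
  res <- mc_slab_cpp(
    thickness_cm = geometry$layers$thickness_mm / 10,
    mu_a = mu_a, mu_sp = mu_sp, n_medium = n_med,
    det_r_lo = r_lo, det_r_hi = r_hi, det_na = det$na,
    n_photons = n_photons, seed = as.integer(seed),
    weight_cutoff = weight_cutoff, fresnel_surface = fresnel_surface
  )
  histories <- photon_history_table(
    detector_id = res$detector_id, L = res$L, Y = res$Y,
    tissue_labels = labels, n_launched = n_photons,
    wavelength_nm = wavelength_nm, detectors = det,
    source = sprintf("layered_slab_mc(seed=%d)", as.integer(seed))
  )
  area_mm2 <- pi * ((r_hi * 10)^2 - (r_lo * 10)^2)
  reflectance <- data.frame(
    id = det$id, sds_mm = det$sds_mm,
    detected_fraction = res$reflectance_weight / n_photons,
    detected_count = res$reflectance_count,
    reflectance_per_mm2 = res$reflectance_weight / n_photons / area_mm2
  )
  if (all(res$reflectance_count == 0)) {
    warning("no photons detected on any detector")
  }
  structure(
    list(
      histories = histories, reflectance = reflectance,
      accounting = list(
        exit_weight_fraction = res$total_exit_weight / n_photons,
        exit_count_fraction = res$total_exit_count / n_photons,
        terminated_fraction = res$terminated_count / n_photons
      ),
      seed = as.integer(seed), n_launched = n_photons
    ),
    class = "mc_run_result"
  )
}

#' @export
print.mc_run_result <- function(x, ...) {
  cat(sprintf(
    "Layered-slab MC: %.3g photons launched, %d detected, seed %d\n",
    x$n_launched, length(x$histories$detector_id), x$seed
  ))
  print(x$reflectance[, c("id", "sds_mm", "detected_count", "reflectance_per_mm2")])
  invisible(x)
}

#' Parametric photon history generator
#'
#' Fast synthetic history tables: per-tissue pathlengths and momentum-transfer
#' values drawn independently from declared distributions. Useful as a light
#' fixture where full transport is not needed.
#'
#' @param spec Named list, one entry per tissue label, each a list with
#'   elements `L` and `Y`, each either a constant or a function `n ->
#'   numeric(n)` sampling the distribution.
#' @param n_rows Number of photons to draw.
#' @param seed Integer RNG seed.
#' @param wavelength_nm Metadata wavelength.
#' @param sds_mm Nominal separation recorded for the single synthetic detector.
#' @return A [photon_history_table()] with `detector_id = 1` throughout and
#'   source marked `"synthetic-parametric"`.
#' @export
parametric_histories <- function(spec, n_rows, seed, wavelength_nm = 850,
                                 sds_mm = 25) {
  if (n_rows < 1) stop("n_rows must be >= 1")
  labels <- names(spec)
  if (is.null(labels)) stop("spec must be a named list of per-tissue entries")
  draw <- function(d) {
    if (is.function(d)) {
      v <- d(n_rows)
      if (length(v) != n_rows) stop("sampler returned wrong length")
      v
    } else {
      rep(as.numeric(d), n_rows)
    }
  }
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  L <- vapply(labels, function(l) draw(spec[[l]]$L), numeric(n_rows))
  Y <- vapply(labels, function(l) draw(spec[[l]]$Y), numeric(n_rows))
  if (n_rows == 1) { L <- matrix(L, 1); Y <- matrix(Y, 1) }
  if (any(L < 0) || any(Y < 0)) stop("sampled pathlengths/momentum transfer must be >= 0")
  photon_history_table(
    detector_id = rep(1L, n_rows), L = L, Y = Y, tissue_labels = labels,
    n_launched = n_rows, wavelength_nm = wavelength_nm,
    detectors = data.frame(id = 1L, sds_mm = sds_mm, radius_mm = 1, na = 1),
    source = "synthetic-parametric"
  )
}

# Scoped seeding helpers: set the RNG deterministically, restore afterwards.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic child seed from a root seed and a stream index (kept < 2^31).
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483563) + 1L
}
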