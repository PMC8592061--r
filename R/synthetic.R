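# Synthetic fMRI cohort generator. Provides a truth surface for the pipeline:
# every subject's ROI voxels carry one of K shared cluster signals (standard
# normal series, fixed per cohort) scaled by an SNR amplitude and a per-subject
# gain, plus unit-variance white noise. No hemodynamic model is attempted: the
# clustering operates on arbitrary time courses, so the simplest model with a
# controllable separability knob is used.

.axisDim <- c(longitudinal = 1L, mediolateral = 2L, dorsoventral = 3L)

deriveSeed <- function(base, salt) {
  as.integer((as.double(base) %% 2147483629 * 48271 + salt) %% 2147483629)
}

#' Construct a ground-truth parcellation
#'
#' Builds an ellipsoidal ROI inscribed in the grid and splits its bounding
#' range along the chosen anatomical axis into `KTrue` equal-width slabs.
#' Axis convention: longitudinal = 1st grid dimension (anterior-posterior),
#' mediolateral = 2nd, dorsoventral = 3rd.
#'
#' @param dims integer(3) grid dimensions of the ROI box.
#' @param KTrue number of ground-truth compartments (>= 1).
#' @param axis one of "longitudinal", "dorsoventral", "mediolateral".
#' @param geom optional [VolumeGeometry-class]; default unit voxels.
#' @return a [GroundTruthParcellation-class].
#' @examples
#' gt <- makeGroundTruth(c(20, 10, 10), KTrue = 2, axis = "longitudinal")
#' table(truthLabels(gt)[gt@mask])
#' @export
makeGroundTruth <- function(dims, KTrue,
                            axis = c("longitudinal", "dorsoventral",
                                     "mediolateral"),
                            geom = NULL) {
  axis <- match.arg(axis)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), KTrue >= 1L)
  if (is.null(geom)) geom <- VolumeGeometry(dims)

  ctr <- (dims + 1) / 2
  rad <- dims / 2
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  inside <- ((g$i - ctr[1]) / rad[1])^2 + ((g$j - ctr[2]) / rad[2])^2 +
    ((g$k - ctr[3]) / rad[3])^2 <= 1
  mask <- array(inside, dim = dims)  # expand.grid order is column-major

  a <- .axisDim[[axis]]
  vl <- which(mask, arr.ind = TRUE)
  vals <- vl[, a]
  lo <- min(vals); hi <- max(vals)
  width <- (hi - lo + 1) / KTrue
  labs <- pmin(KTrue, floor((vals - lo) / width) + 1L)
  if (!all(seq_len(KTrue) %in% labs))
    hippStop("degenerateGeometryError",
             sprintf("cannot fit %d nonempty slabs along the %s axis (%d planes available)",
                     KTrue, axis, hi - lo + 1L))
  labelVol <- array(0L, dim = dims)
  labelVol[vl] <- as.integer(labs)
  new("GroundTruthParcellation", mask = mask, labels = labelVol,
      axis = axis, KTrue = as.integer(KTrue), geometry = geom)
}

# Embed a hemisphere-box truth into a larger grid at a (0-based) offset.
embedTruth <- function(truth, fullDims, offset, geom = NULL) {
  fullDims <- as.integer(fullDims)
  if (is.null(geom)) geom <- VolumeGeometry(fullDims)
  mask <- array(FALSE, fullDims)
  labels <- array(0L, fullDims)
  d <- dim(truth@mask)
  ix <- offset[1] + seq_len(d[1]); iy <- offset[2] + seq_len(d[2])
  iz <- offset[3] + seq_len(d[3])
  mask[ix, iy, iz] <- truth@mask
  labels[ix, iy, iz] <- truth@labels
  new("GroundTruthParcellation", mask = mask, labels = labels,
      axis = truth@axis, KTrue = truth@KTrue, geometry = geom)
}

#' Shared cluster signal series
#'
#' One standard-normal time series per ground-truth compartment, fixed per
#' cohort seed and shared across subjects. Optional AR(1) temporal smoothing
#' (unit stationary variance), off by default.
#'
#' @param K number of compartments.
#' @param nTimepoints series length.
#' @param seed RNG seed.
#' @param ar AR(1) coefficient in \[0, 1); 0 disables smoothing.
#' @return K x nTimepoints matrix.
#' @export
clusterSignals <- function(K, nTimepoints, seed, ar = 0) {
  set.seed(seed)
  sig <- matrix(stats::rnorm(K * nTimepoints), nrow = K)
  if (ar > 0) {
    for (k in seq_len(K)) {
      e <- sig[k, ] * sqrt(1 - ar^2)
      e[1] <- sig[k, 1]
      sig[k, ] <- stats::filter(e, ar, method = "recursive")
    }
  }
  sig
}

#' Simulate one subject's 4D volume
#'
#' In-mask voxel with label k receives
#' `subjectGain * snr * s_k(t) + eps(t)` where `s_k` are the shared cluster
#' signals and `eps` is unit-variance white noise; out-of-mask voxels are
#' all-zero series. Bit-reproducible for a given seed.
#'
#' @param truth a [GroundTruthParcellation-class].
#' @param nTimepoints number of timepoints T (>= 2).
#' @param snr signal amplitude over unit noise SD (>= 0).
#' @param seed RNG seed for the noise (and, if `signals` is NULL, the signals).
#' @param subjectGain per-subject amplitude multiplier.
#' @param signals optional K x T matrix from [clusterSignals()]; pass the same
#'   matrix to every subject of a cohort.
#' @param ar AR(1) coefficient used only when `signals` is NULL.
#' @return 4D array (dims x T).
#' @export
simulateSubject <- function(truth, nTimepoints, snr, seed, subjectGain = 1,
                            signals = NULL, ar = 0) {
  stopifnot(nTimepoints >= 2L, snr >= 0)
  if (is.null(signals))
    signals <- clusterSignals(truth@KTrue, nTimepoints, seed, ar = ar)
  stopifnot(nrow(signals) == truth@KTrue, ncol(signals) == nTimepoints)
  set.seed(deriveSeed(seed, 1L))
  lin <- which(truth@mask)
  labs <- truth@labels[truth@mask]
  n <- length(lin)
  noise <- matrix(stats::rnorm(n * nTimepoints), nrow = n)
  X <- subjectGain * snr * signals[labs, , drop = FALSE] + noise
  flat <- matrix(0, prod(dim(truth@mask)), nTimepoints)
  flat[lin, ] <- X
  array(flat, dim = c(dim(truth@mask), nTimepoints))
}

#' Cohort simulation configuration
#'
#' Defaults describe a moderate-separability resting-style cohort: T = 100
#' timepoints, SNR 0.35 (calibrated so that, at the package's reference
#' geometry of roughly 300 ROI voxels and 20 subjects, mean individual-vs-
#' group similarity lands in the low 0.6s -- the range typical of group
#' parcellation studies), 20 percent inter-subject gain spread, and a
#' right-hemisphere SNR multiplier of 0.7 so the right parcellation is
#' noisier (hence less stable) than the left.
#'
#' @param nSubjects number of subjects M.
#' @param baseSeed integer master seed; all per-subject/condition seeds derive
#'   from it deterministically.
#' @param conditions list of conditions, each `list(name=, axis=, KTrue=)`.
#' @param nTimepoints timepoints per condition.
#' @param snr cluster-signal amplitude over unit noise SD.
#' @param subjectGainSd SD of the per-subject gain `1 + N(0, sd^2)`,
#'   truncated below at 0.1; multiplies signal only.
#' @param hemiDims integer(3) dims of one hemisphere's ROI box.
#' @param hemiSnr named numeric SNR multipliers per hemisphere.
#' @param ar AR(1) smoothing of the cluster signals; 0 = white.
#' @param atlasJitter probability of eroding each subject's mask-boundary
#'   voxels when building the probabilistic atlas (0 = degenerate atlas,
#'   exactly 1 inside the shared mask).
#' @return a `SimulationConfig` object.
#' @export
SimulationConfig <- function(nSubjects, baseSeed,
                             conditions = list(list(name = "rest",
                                                    axis = "dorsoventral",
                                                    KTrue = 3L)),
                             nTimepoints = 100L, snr = 0.35,
                             subjectGainSd = 0.2,
                             hemiDims = c(12L, 8L, 8L),
                             hemiSnr = c(left = 1, right = 0.7),
                             ar = 0, atlasJitter = 0) {
  new("SimulationConfig", nSubjects = as.integer(nSubjects),
      nTimepoints = as.integer(nTimepoints), snr = snr,
      subjectGainSd = subjectGainSd, baseSeed = as.integer(baseSeed),
      conditions = conditions, hemiDims = as.integer(hemiDims),
      hemiSnr = hemiSnr, ar = ar, atlasJitter = atlasJitter)
}

#' @rdname SimulationConfig
#' @slot nSubjects,nTimepoints,snr,subjectGainSd,baseSeed,conditions,hemiDims,hemiSnr,ar,atlasJitter see the constructor arguments.
#' @export
setClass("SimulationConfig",
  representation(nSubjects = "integer", nTimepoints = "integer",
                 snr = "numeric", subjectGainSd = "numeric",
                 baseSeed = "integer", conditions = "list",
                 hemiDims = "integer", hemiSnr = "numeric",
                 ar = "numeric", atlasJitter = "numeric"),
  validity = function(object) {
    if (object@nSubjects < 1L) return("need at least one subject")
    if (object@nTimepoints < 2L) return("need at least two timepoints")
    if (object@snr < 0) return("snr must be nonnegative")
    if (object@subjectGainSd < 0) return("subjectGainSd must be nonnegative")
    if (length(object@conditions) < 1L) return("need at least one condition")
    ok <- vapply(object@conditions, function(cn)
      all(c("name", "axis", "KTrue") %in% names(cn)), TRUE)
    if (!all(ok)) return("each condition needs name, axis and KTrue")
    if (is.null(names(object@hemiSnr)) || any(names(object@hemiSnr) == ""))
      return("hemiSnr must be named by hemisphere")
    TRUE
  }
)

.erodeMask <- function(mask, prob) {
  d <- dim(mask)
  shift <- function(m, dd, s) {
    out <- array(FALSE, d)
    src <- lapply(seq_len(3), function(x) seq_len(d[x]))
    dst <- src
    src[[dd]] <- src[[dd]] - s
    keep <- src[[dd]] >= 1 & src[[dd]] <= d[dd]
    dst[[dd]] <- dst[[dd]][keep]; src[[dd]] <- src[[dd]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- mask
  for (dd in 1:3) for (s in c(-1L, 1L))
    interior <- interior & shift(mask, dd, s)
  boundary <- which(mask & !interior)
  drop <- boundary[stats::runif(length(boundary)) < prob]
  out <- mask
  out[drop] <- FALSE
  out
}

#' Simulate and write a full cohort
#'
#' Writes, under `outDir`: one uncompressed 4D NIfTI per subject x condition
#' (both hemisphere ROIs embedded side-by-side in a shared grid), one
#' probabilistic atlas per hemisphere (voxelwise fraction of subject masks),
#' one truth label volume per condition x hemisphere, a JSON manifest and a
#' YAML copy of the configuration. Re-running with the same configuration
#' reproduces byte-identical files.
#'
#' @param config a [SimulationConfig] object.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
simulateCohort <- function(config, outDir) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hemis <- names(config@hemiSnr)
  hd <- config@hemiDims
  fullDims <- c(hd[1], length(hemis) * hd[2], hd[3])
  geom <- VolumeGeometry(fullDims)
  M <- config@nSubjects
  Tt <- config@nTimepoints
  subjectIds <- sprintf("sub-%02d", seq_len(M))

  # per-subject gains: one draw per subject, signal-only, truncated at 0.1
  set.seed(deriveSeed(config@baseSeed, 777L))
  gains <- pmax(0.1, 1 + stats::rnorm(M, 0, config@subjectGainSd))

  truths <- list(); files <- list(data = list(), truth = list(), atlas = list())
  for (ci in seq_along(config@conditions)) {
    cn <- config@conditions[[ci]]
    truths[[cn$name]] <- list()
    for (hi in seq_along(hemis)) {
      box <- makeGroundTruth(hd, cn$KTrue, axis = cn$axis)
      off <- c(0L, (hi - 1L) * hd[2], 0L)
      truths[[cn$name]][[hemis[hi]]] <- embedTruth(box, fullDims, off, geom)
    }
  }

  # probabilistic atlas per hemisphere (mask shared across conditions by
  # construction: same ellipsoid regardless of axis/K)
  for (hi in seq_along(hemis)) {
    h <- hemis[hi]
    refMask <- truths[[1]][[h]]@mask
    acc <- array(0, fullDims)
    set.seed(deriveSeed(config@baseSeed, 5000L + hi))
    for (s in seq_len(M)) {
      m <- if (config@atlasJitter > 0)
        .erodeMask(refMask, config@atlasJitter) else refMask
      acc <- acc + m
    }
    atlas <- acc / M
    fn <- sprintf("atlas_hemi-%s.nii", h)
    writeVolume(atlas, geom, file.path(outDir, fn), datatype = "float")
    files$atlas[[h]] <- fn
  }

  for (ci in seq_along(config@conditions)) {
    cn <- config@conditions[[ci]]
    files$truth[[cn$name]] <- list()
    for (hi in seq_along(hemis)) {
      h <- hemis[hi]
      fn <- sprintf("truth_cond-%s_hemi-%s.nii", cn$name, h)
      writeVolume(truths[[cn$name]][[h]]@labels, geom,
                  file.path(outDir, fn), datatype = "int16")
      files$truth[[cn$name]][[h]] <- fn
    }
    sigs <- lapply(seq_along(hemis), function(hi)
      clusterSignals(cn$KTrue, Tt, deriveSeed(config@baseSeed, 100L * ci + hi),
                     ar = config@ar))
    files$data[[cn$name]] <- list()
    for (s in seq_len(M)) {
      vol <- array(0, c(fullDims, Tt))
      for (hi in seq_along(hemis)) {
        h <- hemis[hi]
        hv <- simulateSubject(
          truths[[cn$name]][[h]], Tt,
          snr = config@snr * config@hemiSnr[[h]],
          seed = deriveSeed(config@baseSeed, 10000L + 97L * s + 13L * ci + hi),
          subjectGain = gains[s], signals = sigs[[hi]])
        vol <- vol + hv
      }
      fn <- sprintf("%s_cond-%s.nii", subjectIds[s], cn$name)
      writeVolume(vol, geom, file.path(outDir, fn), datatype = "float")
      files$data[[cn$name]][[subjectIds[s]]] <- fn
    }
  }

  manifest <- list(
    subjects = subjectIds,
    hemispheres = hemis,
    conditions = lapply(config@conditions, function(cn)
      cn[c("name", "axis", "KTrue")]),
    baseSeed = config@baseSeed,
    parameters = list(nTimepoints = Tt, snr = config@snr,
                      subjectGainSd = config@subjectGainSd,
                      hemiSnr = as.list(config@hemiSnr), ar = config@ar,
                      atlasJitter = config@atlasJitter,
                      hemiDims = hd, fullDims = fullDims),
    files = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(list(
    nSubjects = M, nTimepoints = Tt, snr = config@snr,
    subjectGainSd = config@subjectGainSd, baseSeed = config@baseSeed,
    conditions = config@conditions, hemiDims = as.integer(hd),
    hemiSnr = as.list(config@hemiSnr), ar = config@ar,
    atlasJitter = config@atlasJitter), file.path(outDir, "config.yaml"))
  invisible(manifest)
}
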