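#' Synthetic cohort specification
#'
#' Defines the generative conditions for a synthetic resting-state cohort:
#' grid geometry, acquisition length, arm sizes, the planted hub/drug regions,
#' the propensity-to-connectivity gain, and the linear outcome model whose
#' parameters the analysis pipeline is later asked to recover.
#'
#' The signal model is a latent-factor model: every brain voxel loads on a
#' shared network factor (gray-matter loadings alternate in sign on a spatial
#' parity pattern so the factor is not simply the global mean), three local
#' factor blocks add regional structure, surrogate white-matter and ventricle
#' blocks carry their own physiological factors, and i.i.d. Gaussian noise is
#' added everywhere. The planted hub region loads `base + g * pi` on the
#' shared factor, where `pi` is the subject's latent placebo propensity, so
#' hub degree counts in the thresholded graph increase monotonically with
#' `pi`. A second, disjoint region does the same with an independent latent
#' `delta` and feeds the drug component of the outcome model.
#'
#' Outcomes: placebo-arm percent analgesia is `a_true * hub_degree + b_true +
#' noise`; drug-arm analgesia adds `d_true * (drug_degree - drug_deg0)`; the
#' no-treatment arm is noise only; the healthy arm contributes volumes only.
#'
#' @param dim length-3 integer grid (voxels per axis).
#' @param n_volumes number of acquired frames (before discarding).
#' @param tr repetition time, seconds.
#' @param voxel_mm voxel edge lengths, mm.
#' @param arms named integer vector of subject counts; names from
#'   `c("placebo", "drug", "no-treatment", "healthy")`. A modeled arm needs
#'   at least 2 subjects; 0 means absent.
#' @param g propensity-to-connectivity gain (loading units per propensity
#'   unit).
#' @param a_true,b_true planted placebo model: percent analgesia per
#'   degree-count unit, and intercept in percent.
#' @param d_true planted drug slope (percent analgesia per degree-count unit
#'   of the drug region).
#' @param drug_deg0 reference drug-region degree count at which the planted
#'   drug component is zero; the drug component is
#'   `d_true * (drug_degree - drug_deg0)`, so low-connectivity subjects get
#'   essentially no drug effect while the slope in degree units stays
#'   `d_true`.
#' @param noise_sd outcome noise standard deviation, percent analgesia.
#' @param density link density at which ROI degree counts enter the outcome
#'   model.
#' @param seed master seed; per-subject streams are derived from it.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(dim = c(12L, 12L, 12L), n_volumes = 300L, tr = 2.5,
                        voxel_mm = c(4, 4, 4),
                        arms = c(placebo = 17L, drug = 0L,
                                 `no-treatment` = 0L, healthy = 0L),
                        g = 0.35, a_true = 0.65, b_true = -70, d_true = 0.3,
                        drug_deg0 = 110,
                        noise_sd = 10, density = 0.10, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 6))
  if (n_volumes < 50) stop("invalid specification: need at least 50 volumes")
  if (noise_sd < 0) stop("invalid specification: noise sd must be >= 0")
  if (tr <= 0) stop("invalid specification: TR must be positive")
  known <- c("placebo", "drug", "no-treatment", "healthy")
  if (is.null(names(arms)) || !all(names(arms) %in% known))
    stop("arm names must be among: ", paste(known, collapse = ", "))
  arms <- setNames(as.integer(arms[known]), known)
  arms[is.na(arms)] <- 0L
  if (any(arms > 0 & arms < 2 & names(arms) != "healthy"))
    stop("invalid specification: modeled arms need at least 2 subjects")
  geom <- cohort_geometry(dim)
  if (nrow(intersect_coords(geom$hub, geom$drug)) > 0)
    stop("invalid specification: hub and drug regions overlap")
  spec <- structure(
    list(dim = dim, n_volumes = as.integer(n_volumes), tr = tr,
         voxel_mm = as.numeric(voxel_mm), arms = arms, g = g,
         a_true = a_true, b_true = b_true, d_true = d_true,
         drug_deg0 = drug_deg0,
         noise_sd = noise_sd, density = density, seed = as.integer(seed),
         base_loading = 0.3, local_loading = 0.9, phys_loading = 0.9,
         mask = geom$mask, hub = geom$hub, drug = geom$drug,
         locals = geom$locals, wm = geom$wm, csf = geom$csf),
    class = "cohort_spec")
  if (!any(spec$mask)) stop("invalid specification: empty mask")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %dx%dx%d grid, %d frames @ TR %.2gs, %d gray voxels\n",
              x$dim[1], x$dim[2], x$dim[3], x$n_volumes, x$tr, sum(x$mask)))
  cat("  arms:", paste(sprintf("%s=%d", names(x$arms), x$arms), collapse = ", "), "\n")
  cat(sprintf("  planted model: analgesia = %.3g*deg %+.3g (+ %.3g*drugdeg), sd %.3g, g = %.3g\n",
              x$a_true, x$b_true, x$d_true, x$noise_sd, x$g))
  invisible(x)
}

# rectangular block of voxel coordinates centred at rel*dim with half-width hw
block_coords <- function(dim, rel, hw) {
  ctr <- pmax(1 + hw, pmin(dim - hw, round(rel * dim)))
  as.matrix(expand.grid(x = (ctr[1] - hw):(ctr[1] + hw),
                        y = (ctr[2] - hw):(ctr[2] + hw),
                        z = (ctr[3] - hw):(ctr[3] + hw)))
}

intersect_coords <- function(a, b) {
  ka <- paste(a[, 1], a[, 2], a[, 3])
  a[ka %in% paste(b[, 1], b[, 2], b[, 3]), , drop = FALSE]
}

# Brain-like geometry: an ellipsoidal gray-matter mask with planted regions.
# The analysis mask is (ellipsoid plus signal regions) minus the surrogate
# white-matter and ventricle blocks, which serve only as confound sources.
cohort_geometry <- function(dim) {
  hw <- max(1L, dim[1] %/% 10L)
  hub <- block_coords(dim, c(0.29, 0.58, 0.58), hw)
  drug <- block_coords(dim, c(0.79, 0.58, 0.58), hw)
  locals <- list(block_coords(dim, c(0.58, 0.83, 0.58), hw),
                 block_coords(dim, c(0.58, 0.58, 0.29), hw),
                 block_coords(dim, c(0.58, 0.58, 0.83), hw))
  wm <- block_coords(dim, c(0.46, 0.29, 0.54), max(1L, hw - 1L))
  csf <- block_coords(dim, c(0.64, 0.29, 0.54), max(1L, hw - 1L))
  ctr <- (dim + 1) / 2
  rad <- 0.42 * dim
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  inside <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2 <= 1
  mask <- array(FALSE, dim)
  mask[as.matrix(g[inside, ])] <- TRUE
  for (r in c(list(hub, drug), locals)) mask[r] <- TRUE
  mask[wm] <- FALSE
  mask[csf] <- FALSE
  list(mask = mask, hub = hub, drug = drug, locals = locals, wm = wm, csf = csf)
}

# voxels belonging to any signal-carrying compartment (gray + wm + csf)
brain_voxels <- function(spec) {
  b <- spec$mask
  b[spec$wm] <- TRUE
  b[spec$csf] <- TRUE
  b
}

#' Generate one synthetic 4D volume
#'
#' Draws the latent-factor time series and voxel noise for a single subject
#' and assembles the 4D volume described in [cohort_spec()]. Deterministic
#' given `seed`: the same spec and seed always yield bit-identical data.
#'
#' @param spec a [cohort_spec()].
#' @param pi latent placebo propensity (finite, `>= 0`).
#' @param seed integer seed for this subject's stream.
#' @param delta latent drug-region propensity (finite, `>= 0`).
#' @return A [ts_volume()] whose mask is the spec's analysis mask.
#' @export
generate_volume <- function(spec, pi, seed, delta = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.finite(pi) || pi < 0) stop("invalid specification: propensity must be finite and >= 0")
  if (!is.finite(delta) || delta < 0) stop("invalid specification: delta must be finite and >= 0")
  if (!any(spec$mask)) stop("invalid specification: empty mask")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  d <- spec$dim
  T <- spec$n_volumes
  nvox <- prod(d)

  f_g <- rnorm(T)
  f_loc <- matrix(rnorm(T * 3), T, 3)
  f_wm <- rnorm(T)
  f_csf <- rnorm(T)

  # shared-factor loadings: sign-alternating base in gray matter, propensity-
  # scaled positive loading in the planted regions
  gidx <- which(spec$mask)
  co <- arrayInd(gidx, d)
  load_g <- numeric(nvox)
  load_g[gidx] <- spec$base_loading * (-1)^(co[, 1] + co[, 2] + co[, 3])
  hub_idx <- coords_to_idx(spec$hub, d)
  drug_idx <- coords_to_idx(spec$drug, d)
  load_g[hub_idx] <- spec$base_loading + spec$g * pi
  load_g[drug_idx] <- spec$base_loading + spec$g * delta

  X <- tcrossprod(load_g, f_g)                      # nvox x T
  for (k in 1:3) {
    li <- coords_to_idx(spec$locals[[k]], d)
    X[li, ] <- X[li, ] + spec$local_loading * matrix(f_loc[, k], length(li), T, byrow = TRUE)
  }
  wm_idx <- coords_to_idx(spec$wm, d)
  csf_idx <- coords_to_idx(spec$csf, d)
  X[wm_idx, ] <- X[wm_idx, ] + spec$phys_loading * matrix(f_wm, length(wm_idx), T, byrow = TRUE)
  X[csf_idx, ] <- X[csf_idx, ] + spec$phys_loading * matrix(f_csf, length(csf_idx), T, byrow = TRUE)

  brain <- which(brain_voxels(spec))
  noise <- matrix(rnorm(nvox * T), nvox, T)
  noise[-brain, ] <- 0.05 * noise[-brain, ]          # air: faint scanner noise
  X <- X + noise
  X[brain, ] <- X[brain, ] + 100                     # BOLD-like baseline

  dim(X) <- c(d, T)
  ts_volume(X, tr = spec$tr, voxel_mm = spec$voxel_mm, mask = spec$mask)
}

# Latent propensity draw: an equal mixture of a low (uniform on [0, 0.4])
# and a high (uniform on [1.2, 2]) component. The dichotomy emulates the
# bimodal responder/nonresponder structure of placebo-treated cohorts:
# roughly half the subjects carry a hub connectivity high enough to respond.
draw_propensity <- function(n) {
  hi <- runif(n) < 0.5
  ifelse(hi, runif(n, 1.2, 2), runif(n, 0, 0.4))
}

coords_to_idx <- function(coords, dim) {
  coords[, 1] + dim[1] * (coords[, 2] - 1) + dim[1] * dim[2] * (coords[, 3] - 1)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate six synthetic motion-parameter traces
#'
#' Slow random-walk traces standing in for rigid-body realignment estimates;
#' they carry no signal into the volumes but complete the confound set.
#'
#' @param n_frames number of time points.
#' @param seed integer seed.
#' @return An `n_frames x 6` matrix with columns `mot1..mot6`.
#' @export
generate_motion <- function(n_frames, seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  m <- apply(matrix(rnorm(n_frames * 6, sd = 0.02), n_frames, 6), 2, cumsum)
  colnames(m) <- paste0("mot", 1:6)
  m
}

#' Generate a full synthetic cohort
#'
#' Draws one subject per arm slot: latent propensities, a 4D volume, the
#' canonical degree sweep (the same preprocessing + graph pipeline the
#' analysis uses), and a behavioral record whose percent analgesia follows
#' the planted linear model in [cohort_spec()]. Volumes are not retained
#' (they are regenerable from the per-subject seeds); degree sweeps are.
#'
#' @param spec a [cohort_spec()].
#' @param densities density grid for the stored degree sweeps.
#' @param progress print per-subject progress.
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `behavior` (one row per subject), `truth` (latents and planted
#'   analgesia), `degrees` (nodes x densities x subjects array), `nodes`
#'   (node lookup shared by all subjects), `densities`.
#' @export
generate_cohort <- function(spec, densities = density_grid(), progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- sum(spec$arms)
  if (n_tot < 1) stop("invalid specification: no subjects requested")
  arm_of <- rep(names(spec$arms), spec$arms)
  ids <- sprintf("s%03d", seq_len(n_tot))

  degrees <- NULL
  nodes <- NULL
  beh <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  d10 <- which.min(abs(densities - spec$density))
  if (abs(densities[d10] - spec$density) > 1e-9)
    densities <- sort(unique(c(densities, spec$density)))
  d10 <- which.min(abs(densities - spec$density))

  for (i in seq_len(n_tot)) {
    s_i <- subject_seed(spec$seed, i)
    old <- globalenv()$.Random.seed
    set.seed(s_i + 1L)
    lat <- draw_propensity(2)                  # pi, delta
    covar <- list(
      age = round(rnorm(1, 58, 7)),
      gender = sample(c("F", "M"), 1),
      duration = round(1 + rgamma(1, shape = 2, scale = 4), 1),
      bdi = rpois(1, 6),
      pcs = rpois(1, 15),
      mqs = round(rgamma(1, shape = 2, scale = 3), 1),
      vas_pre = runif(3, 4, 9),                # entry criterion: pain >= 4/10
      womac_pre = runif(1, 35, 65),
      eps = rnorm(2, 0, spec$noise_sd)         # VAS noise, WOMAC extra noise
    )
    restore_rng(old)

    vol <- generate_volume(spec, pi = lat[1], seed = s_i, delta = lat[2])
    sw <- canonical_degree_sweep(vol, spec, densities)
    if (is.null(degrees)) {
      nodes <- sw$nodes
      degrees <- array(0L, c(nrow(sw$degree), length(densities), n_tot),
                       dimnames = list(NULL, paste0("d", densities), ids))
    }
    degrees[, , i] <- sw$degree

    hub_deg <- mean(sw$degree[node_index(nodes, spec$hub), d10])
    drug_deg <- mean(sw$degree[node_index(nodes, spec$drug), d10])

    arm <- arm_of[i]
    planted <- switch(arm,
      placebo = spec$a_true * hub_deg + spec$b_true,
      drug = spec$a_true * hub_deg + spec$b_true +
        spec$d_true * (drug_deg - spec$drug_deg0),
      `no-treatment` = 0,
      healthy = NA_real_)
    analgesia <- if (is.na(planted)) NA_real_ else planted + covar$eps[1]
    vas_pre_m <- mean(covar$vas_pre)
    vas_post <- if (is.na(analgesia)) NA_real_ else
      min(10, max(0, vas_pre_m * (1 - analgesia / 100)))
    wom_analg <- if (is.na(analgesia)) NA_real_ else
      0.7 * analgesia + 0.5 * covar$eps[2]
    womac_post <- if (is.na(wom_analg)) NA_real_ else
      min(100, max(0, covar$womac_pre * (1 - wom_analg / 100)))

    beh[[i]] <- data.frame(
      id = ids[i], arm = arm,
      vas_pre_1 = covar$vas_pre[1], vas_pre_2 = covar$vas_pre[2],
      vas_pre_3 = covar$vas_pre[3], vas_post = vas_post,
      womac_pre = covar$womac_pre, womac_post = womac_post,
      age = covar$age, gender = covar$gender, duration = covar$duration,
      bdi = covar$bdi, pcs = covar$pcs, mqs = covar$mqs,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      id = ids[i], arm = arm, pi = lat[1], delta = lat[2],
      hub_degree = hub_deg, drug_degree = drug_deg,
      planted_analgesia = planted, seed = s_i, stringsAsFactors = FALSE)
    if (progress) message(sprintf("subject %s (%s) done", ids[i], arm))
  }

  structure(list(spec = spec, behavior = do.call(rbind, beh),
                 truth = do.call(rbind, truth), degrees = degrees,
                 nodes = nodes, densities = densities),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes, %d densities\n",
              nrow(x$behavior), dim(x$degrees)[1], dim(x$degrees)[2]))
  print(table(x$behavior$arm))
  invisible(x)
}

#' Canonical preprocessing + degree sweep for one subject
#'
#' The fixed order used throughout: discard 5 initial frames, 5 mm FWHM
#' Gaussian smoothing, 150 s high-pass, confound regression (shared-network
#' surrogate global mean plus white-matter/ventricle means and motion
#' traces), masking, then the density sweep of degree maps.
#'
#' @param vol a [ts_volume()].
#' @param spec the [cohort_spec()] providing surrogate WM/CSF regions and the
#'   subject seed base for motion traces.
#' @param densities ascending density grid.
#' @param discard,fwhm_mm,hp_s preprocessing parameters.
#' @return list with `degree` (nodes x densities integer matrix), `nodes`
#'   lookup, `densities`.
#' @export
canonical_degree_sweep <- function(vol, spec, densities = density_grid(),
                                   discard = 5L, fwhm_mm = 5, hp_s = 150) {
  v <- discard_initial_volumes(vol, discard)
  v <- spatial_smooth(v, fwhm_mm)
  v <- highpass_filter(v, hp_s)
  conf <- extract_confounds(v, wm_region = spec$wm, csf_region = spec$csf)
  v <- regress_confounds(v, conf)
  nts <- mask_and_downsample(v, v$mask, factor = 1L)
  sw <- degree_sweep(nts$series, densities)
  list(degree = sw$degree, nodes = nts, densities = densities)
}

#' The standard link-density grid
#'
#' Ten densities from 2\% to 20\% in 2\% steps.
#' @return numeric vector of densities (fractions).
#' @export
density_grid <- function() seq(0.02, 0.20, by = 0.02)

# rows of the node lookup corresponding to a voxel-coordinate region
node_index <- function(nodes, coords) {
  key <- paste(nodes$coords[, 1], nodes$coords[, 2], nodes$coords[, 3])
  idx <- match(paste(coords[, 1], coords[, 2], coords[, 3]), key)
  idx[!is.na(idx)]
}

#' Write a cohort to disk (NIfTI volumes + mask + behavioral CSV)
#'
#' Regenerates each subject's 4D volume from its recorded seed and writes it
#' as NIfTI, together with the shared binary mask and the behavioral table.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort$spec
  for (i in seq_len(nrow(cohort$truth))) {
    tr_row <- cohort$truth[i, ]
    vol <- generate_volume(spec, pi = tr_row$pi, seed = tr_row$seed,
                           delta = tr_row$delta)
    write_volume_nifti(vol, file.path(dir, paste0(tr_row$id, ".nii.gz")))
  }
  m <- RNifti::asNifti(array(as.numeric(spec$mask), spec$dim))
  m <- RNifti::`pixdim<-`(m, spec$voxel_mm)
  RNifti::writeNifti(m, file.path(dir, "mask.nii.gz"))
  utils::write.csv(cohort$behavior, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
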