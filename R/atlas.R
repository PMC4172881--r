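#' Spatially normalise an atlas set into a common reference frame
#'
#' One atlas is chosen as the reference; every atlas is moment-aligned to
#' the reference's label map (centroid + principal axes + per-axis scale),
#' its image resampled linearly and its label nearest-neighbour onto the
#' reference grid.
#'
#' @param atlases list of `list(image, label)` pairs as produced by
#'   [generate_atlas_set()].
#' @param reference_index which atlas defines the common frame (default 1).
#' @return object of class `normalized_atlas_set`: `reference_index`,
#'   `images`, `labels`, `transforms` (one [affine_transform()] per atlas,
#'   reference world -> atlas world).
#' @export
normalize_atlases <- function(atlases, reference_index = 1L) {
  if (length(atlases) < 2L) stop("need at least 2 atlases")
  ref <- atlases[[reference_index]]
  out <- list(reference_index = reference_index,
              images = vector("list", length(atlases)),
              labels = vector("list", length(atlases)),
              transforms = vector("list", length(atlases)))
  for (i in seq_along(atlases)) {
    if (i == reference_index) {
      tr <- affine_transform()
    } else {
      tr <- tryCatch(align_by_moments(atlases[[i]]$label, ref$label),
                     error = function(e)
                       stop("atlas ", i, ": ", conditionMessage(e)))
    }
    out$transforms[[i]] <- tr
    out$images[[i]] <- resample(atlases[[i]]$image, tr, ref$image, "linear")
    out$labels[[i]] <- resample(atlases[[i]]$label, tr, ref$label, "nearest")
  }
  class(out) <- "normalized_atlas_set"
  out
}

#' @export
print.normalized_atlas_set <- function(x, ...) {
  cat(sprintf("<normalized_atlas_set> %d atlases, reference %d, grid %s\n",
              length(x$images), x$reference_index,
              paste(dim(x$images[[1]]$values), collapse = "x")))
  invisible(x)
}

#' Voxelwise statistical parameter maps of the probabilistic atlas
#'
#' For each label l in \{0,1\} and each voxel, the mean and unbiased
#' variance of the aligned atlas intensities carrying that label there, plus
#' the voting label prior `count1 / N`. Where fewer than one (mean) or two
#' (variance) atlases carry a label, the global mean/variance of that label
#' over the whole aligned set fills in. Both maps are then smoothed at
#' scale `sigma_s` voxels (normalised Gaussian, reflective/Neumann
#' boundaries) by diffusing the sufficient statistics: the smoothed
#' variance is `smooth(var + mu^2) - smooth(mu)^2`, so it absorbs the local
#' dispersion of the mean map and the appearance model stays calibrated
#' where the mean varies spatially. `sigma_s = 0` leaves the empirical maps
#' untouched. Variances are floored at `(0.01 * intensity range)^2` and the
#' prior is clamped to `[eps, 1 - eps]` with `eps = 1/(2N)` so unary costs
#' stay finite.
#'
#' @param aligned a [normalize_atlases()] result (or any list with `images`
#'   and `labels` on a shared grid).
#' @param sigma_s smoothing scale in voxels (default 2).
#' @return object of class `stat_param_maps`: arrays `mu0, mu1, var0, var1,
#'   prior1, count0, count1`, plus `n_atlases`, `sigma_s`, `epsilon`,
#'   `var_floor` and the grid metadata.
#' @export
build_stat_maps <- function(aligned, sigma_s = 2) {
  imgs <- aligned$images; labs <- aligned$labels
  N <- length(imgs)
  d <- dim(imgs[[1]]$values)
  sum1 <- array(0, d); sum0 <- array(0, d)
  ss1 <- array(0, d); ss0 <- array(0, d)
  cnt1 <- array(0, d)
  for (i in seq_len(N)) {
    v <- imgs[[i]]$values; l <- labs[[i]]$values
    sum1 <- sum1 + v * l; ss1 <- ss1 + v^2 * l
    sum0 <- sum0 + v * (1 - l); ss0 <- ss0 + v^2 * (1 - l)
    cnt1 <- cnt1 + l
  }
  cnt0 <- N - cnt1
  rng <- range(vapply(imgs, function(im) range(im$values), numeric(2)))
  var_floor <- (0.01 * max(rng[2] - rng[1], 1e-6))^2
  glob <- function(s, ss, n) {
    tot_n <- sum(n); tot_s <- sum(s); tot_ss <- sum(ss)
    mu <- if (tot_n > 0) tot_s / tot_n else mean(rng)
    vv <- if (tot_n > 1) (tot_ss - tot_n * mu^2) / (tot_n - 1) else var_floor
    c(mu, max(vv, var_floor))
  }
  g1 <- glob(sum1, ss1, cnt1); g0 <- glob(sum0, ss0, cnt0)
  emp <- function(s, ss, n, g) {
    mu <- ifelse(n >= 1, s / pmax(n, 1), g[1])
    vv <- ifelse(n >= 2, (ss - n * mu^2) / pmax(n - 1, 1), g[2])
    list(mu = array(mu, d), var = array(pmax(vv, 0), d))
  }
  e1 <- emp(sum1, ss1, cnt1, g1); e0 <- emp(sum0, ss0, cnt0, g0)
  # diffuse the sufficient statistics: the smoothed variance picks up the
  # local dispersion of the mean map (law of total variance), keeping the
  # Gaussian appearance model calibrated where the mean varies spatially —
  # smoothing mean and variance independently makes it overconfident there
  sm_pair <- function(e) {
    if (sigma_s <= 0) return(e)
    m1 <- gaussian_smooth(e$mu, sigma_s)
    m2 <- gaussian_smooth(e$var + e$mu^2, sigma_s)
    list(mu = m1, var = pmax(m2 - m1^2, 0))
  }
  s0 <- sm_pair(e0); s1 <- sm_pair(e1)
  eps <- 1 / (2 * N)
  out <- list(
    mu0 = s0$mu, mu1 = s1$mu,
    var0 = pmax(s0$var, var_floor), var1 = pmax(s1$var, var_floor),
    prior1 = array(pmin(pmax(cnt1 / N, eps), 1 - eps), d),
    count0 = array(as.integer(round(cnt0)), d),
    count1 = array(as.integer(round(cnt1)), d),
    n_atlases = N, sigma_s = sigma_s, epsilon = eps, var_floor = var_floor,
    spacing = imgs[[1]]$spacing, origin = imgs[[1]]$origin, dim = d)
  class(out) <- "stat_param_maps"
  out
}

#' @export
print.stat_param_maps <- function(x, ...) {
  cat(sprintf(paste0("<stat_param_maps> N = %d atlases, grid %s, ",
                     "sigma_s = %g voxels\n"),
              x$n_atlases, paste(x$dim, collapse = "x"), x$sigma_s))
  invisible(x)
}

#' Per-voxel label likelihoods under the appearance model
#'
#' Evaluates, at every voxel, the per-label Gaussian appearance densities
#' `exp(-(I - mu_l)^2 / (2 var_l)) / sigma_l` and normalises them so
#' `p0 + p1 = 1`.
#'
#' @param maps a [build_stat_maps()] result.
#' @param intensity 3-D array (or [volume_grid()]) of target intensities on
#'   the maps' grid.
#' @return list of arrays `p0`, `p1` summing to one voxelwise.
#' @export
label_likelihood <- function(maps, intensity) {
  if (inherits(intensity, "volume_grid")) intensity <- intensity$values
  if (!identical(dim(intensity), maps$dim))
    stop("intensity grid does not match the statistical maps")
  # log-densities, stabilised before exponentiation
  l0 <- -(intensity - maps$mu0)^2 / (2 * maps$var0) - 0.5 * log(maps$var0)
  l1 <- -(intensity - maps$mu1)^2 / (2 * maps$var1) - 0.5 * log(maps$var1)
  m <- pmax(l0, l1)
  e0 <- exp(l0 - m); e1 <- exp(l1 - m)
  z <- e0 + e1
  list(p0 = e0 / z, p1 = e1 / z)
}

#' Persist / load statistical parameter maps
#'
#' Writes the maps as a directory of NIfTI volumes plus a JSON sidecar with
#' `N`, `sigma_s`, `epsilon` and the variance floor.
#'
#' @param maps a [build_stat_maps()] result.
#' @param dir directory to create.
#' @return `dir` invisibly; `read_stat_maps()` returns the maps.
#' @export
write_stat_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mu0", "mu1", "var0", "var1", "prior1")) {
    write_volume(volume_grid(maps[[nm]], maps$spacing, maps$origin),
                 file.path(dir, paste0(nm, ".nii.gz")))
  }
  for (nm in c("count0", "count1")) {
    write_volume(volume_grid(array(as.numeric(maps[[nm]]), maps$dim),
                             maps$spacing, maps$origin),
                 file.path(dir, paste0(nm, ".nii.gz")))
  }
  jsonlite::write_json(list(N = maps$n_atlases, sigma_s = maps$sigma_s,
                            epsilon = maps$epsilon, floor = maps$var_floor),
                       file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_stat_maps
#' @export
read_stat_maps <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  vols <- lapply(c("mu0", "mu1", "var0", "var1", "prior1", "count0",
                   "count1"),
                 function(nm) read_volume(file.path(dir, paste0(nm, ".nii.gz"))))
  maps <- list(mu0 = vols[[1]]$values, mu1 = vols[[2]]$values,
               var0 = vols[[3]]$values, var1 = vols[[4]]$values,
               prior1 = vols[[5]]$values,
               count0 = array(as.integer(round(vols[[6]]$values)),
                              dim(vols[[6]]$values)),
               count1 = array(as.integer(round(vols[[7]]$values)),
                              dim(vols[[7]]$values)),
               n_atlases = side$N, sigma_s = side$sigma_s,
               epsilon = side$epsilon, var_floor = side$floor,
               spacing = vols[[1]]$spacing, origin = vols[[1]]$origin,
               dim = dim(vols[[1]]$values))
  class(maps) <- "stat_param_maps"
  maps
}
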