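#' Configuration of the total-tumor-burden pipeline
#'
#' Defaults follow the published workflow: 3-D region growing at 10% of the
#' global maximum to find candidate objects, per-object segmentation at 42%
#' of the object's maximum, additional peaks admitted at 20% of the object's
#' maximum and segmented at 42% of their own local maxima, and a minimum VOI
#' volume of 0.3 ml.
#'
#' @param grow_percent candidate-detection threshold, fraction of the global
#'   maximum (default 0.10).
#' @param local_percent per-object threshold, fraction of the (local) peak
#'   (default 0.42).
#' @param secondary_peak_percent minimum residual-peak height as a fraction
#'   of the object's maximum (default 0.20).
#' @param min_volume_ml VOIs must strictly exceed this volume (default 0.3).
#' @param mode `"percent"` or `"absolute_suv"`.
#' @param absolute_suv fixed SUV threshold used in `absolute_suv` mode.
#' @param exclusions list of [constraint_region()] removed before candidate
#'   detection (brain, bladder, ...). Only `"inside"` regions are excluded.
#' @return An object of class `burden_config`.
#' @export
burden_config <- function(grow_percent = 0.10, local_percent = 0.42,
                          secondary_peak_percent = 0.20, min_volume_ml = 0.3,
                          mode = c("percent", "absolute_suv"),
                          absolute_suv = NULL, exclusions = list()) {
  mode <- match.arg(mode)
  if (!(grow_percent > 0 && grow_percent < local_percent && local_percent <= 1))
    stop("need 0 < grow_percent < local_percent <= 1")
  if (min_volume_ml < 0) stop("min_volume_ml must be >= 0")
  if (mode == "absolute_suv" && is.null(absolute_suv))
    stop("absolute_suv mode needs an absolute_suv value")
  structure(list(grow_percent = grow_percent, local_percent = local_percent,
                 secondary_peak_percent = secondary_peak_percent,
                 min_volume_ml = min_volume_ml, mode = mode,
                 absolute_suv = absolute_suv, exclusions = exclusions),
            class = "burden_config")
}

#' Stage 1: detect candidate lesion objects by region growing
#'
#' Voxels at or above `grow_percent` of the global maximum (computed over the
#' non-excluded space) are labeled into 26-connected objects. Exclusion
#' regions are removed before labeling, so high physiological uptake (brain,
#' bladder) never seeds a candidate.
#'
#' @param pet an [image_volume()] (SUV or activity concentration).
#' @param cfg a [burden_config()].
#' @return A list of `segment_object`s (possibly empty).
#' @export
detect_candidates <- function(pet, cfg = burden_config()) {
  allowed <- array(TRUE, pet$geometry$dims)
  for (ex in cfg$exclusions) {
    m <- allowed_mask(ex, pet$geometry)
    allowed <- allowed & m
  }
  if (all(pet$voxels[allowed] == 0)) return(list())
  thr <- cfg$grow_percent * max(pet$voxels[allowed])
  fg <- (pet$voxels >= thr) & allowed
  objs <- label_objects(voi_mask(fg, pet$geometry, "candidates"), pet, 26L)
  for (i in seq_along(objs)) objs[[i]]$provenance <- "detect_candidates"
  objs
}

# 26-neighborhood local maxima among linear indices `vox`, with the
# neighborhood comparison taken over `domain` (defaults to `vox`): a voxel
# adjacent to a higher-valued domain voxel is never a local maximum, even if
# that neighbor has already been segmented away
local_maxima_in <- function(vol, vox, domain = vox) {
  d <- dim(vol$voxels)
  inside <- array(FALSE, d); inside[domain] <- TRUE
  v <- vol$voxels
  is_max <- rep(TRUE, length(vox))
  pos <- arrayInd(vox, d)
  off <- neighbor_offsets(26L)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(pos, 2, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    use <- ok
    use[ok] <- inside[nlin]
    cmp <- rep(-Inf, length(vox))
    cmp[use] <- v[nlin[inside[nlin]]]
    is_max <- is_max & v[vox] >= cmp
  }
  vox[is_max]
}

# region of voxels (within `candidate` linear indices) with value >= thr,
# 26-connected to the seed linear index
grow_region <- function(vol, candidate, thr, seed) {
  d <- dim(vol$voxels)
  ok <- candidate[vol$voxels[candidate] >= thr]
  m <- array(FALSE, d); m[ok] <- TRUE
  lab <- label_array(m, 26L)
  sel <- lab == lab[seed]
  if (lab[seed] == 0L) sel <- array(FALSE, d)  # seed below threshold
  which(sel)
}

#' Stage 2: segment one candidate object into per-peak VOIs
#'
#' In percent mode the object is thresholded at `local_percent` of its
#' maximum, keeping the region connected to the peak. The residual (object
#' minus segmented regions) is then searched for additional peaks: local
#' maxima of the volume at or above `secondary_peak_percent` of the object's
#' maximum, each segmented at `local_percent` of its own local maximum,
#' iterating highest-first until no qualifying residual peak remains. In
#' `absolute_suv` mode the object is thresholded at the fixed SUV.
#'
#' @param pet the [image_volume()] the object came from.
#' @param obj a `segment_object` from [detect_candidates()].
#' @param cfg a [burden_config()].
#' @return A list of [voi_mask()]s (pairwise disjoint subsets of the object).
#' @export
segment_object <- function(pet, obj, cfg = burden_config()) {
  g <- pet$geometry
  if (cfg$mode == "absolute_suv") {
    m <- array(FALSE, g$dims)
    m[obj$voxels[pet$voxels[obj$voxels] >= cfg$absolute_suv]] <- TRUE
    if (!any(m)) return(list())
    return(list(voi_mask(m, g, sprintf("obj%02d_abs", obj$id))))
  }
  obj_peak <- obj$peak_value
  residual <- obj$voxels
  vois <- list()
  repeat {
    if (!length(residual)) break
    cand <- local_maxima_in(pet, residual, domain = obj$voxels)
    if (!length(cand)) break
    seed <- cand[which.max(pet$voxels[cand])]
    peak_v <- pet$voxels[seed]
    # the first region uses the object's own maximum; later ones must clear
    # the secondary-peak rule
    if (length(vois) > 0 && peak_v < cfg$secondary_peak_percent * obj_peak)
      break
    reg <- grow_region(pet, residual, cfg$local_percent * peak_v, seed)
    if (!length(reg)) break
    m <- array(FALSE, g$dims); m[reg] <- TRUE
    vois[[length(vois) + 1]] <-
      voi_mask(m, g, sprintf("obj%02d_p%02d", obj$id, length(vois) + 1))
    residual <- setdiff(residual, reg)
  }
  vois
}

#' Stage 2b: minimum-volume filter
#'
#' VOIs must strictly exceed `min_volume_ml` to be included.
#'
#' @param vois list of [voi_mask()].
#' @param cfg a [burden_config()].
#' @return The surviving VOIs.
#' @export
filter_small <- function(vois, cfg = burden_config()) {
  if (!length(vois)) return(vois)
  keep <- vapply(vois, function(v)
    sum(v$mask) * voxel_volume_ml(v$geometry) > cfg$min_volume_ml, logical(1))
  vois[keep]
}

#' Run the full total-tumor-burden pipeline
#'
#' Candidate detection, per-object peak segmentation, and the minimum-volume
#' filter, returning VOIs ordered superior to inferior (by centroid S
#' coordinate) for sequential review.
#'
#' @param pet an [image_volume()] (SUV or activity concentration).
#' @param cfg a [burden_config()].
#' @return An object of class `burden_result` with fields `vois`,
#'   `statistics` (list of [compute_statistics()] rows), `candidate_objects`,
#'   `deleted_ids`, `pet_geometry`.
#' @export
total_tumor_burden <- function(pet, cfg = burden_config()) {
  objs <- detect_candidates(pet, cfg)
  vois <- list()
  for (o in objs) vois <- c(vois, segment_object(pet, o, cfg))
  vois <- filter_small(vois, cfg)
  if (length(vois)) {
    s_coord <- vapply(vois, function(v) {
      w <- which(v$mask, arr.ind = TRUE)
      mean(voxel_to_world(v$geometry, w - 1L, check = FALSE)[, 3])
    }, numeric(1))
    vois <- vois[order(s_coord, decreasing = TRUE)]  # superior first
  }
  for (i in seq_along(vois)) vois[[i]]$name <- sprintf("VOI_%02d", i)
  structure(list(vois = vois,
                 statistics = lapply(vois, function(v) compute_statistics(pet, v)),
                 candidate_objects = objs,
                 deleted_ids = character(0),
                 pet_geometry = pet$geometry),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("burden_result: %d VOIs (%d candidate objects, %d deleted)\n",
              length(x$vois), length(x$candidate_objects),
              length(x$deleted_ids)))
  for (s in x$statistics) print(s)
  invisible(x)
}

#' Stage 3: delete a VOI during sequential review
#'
#' Removes the VOI from the result (and hence from the aggregated global
#' mask) and records its id. Deleting an unknown or already-deleted id is an
#' error.
#'
#' @param result a `burden_result`.
#' @param voi_id the VOI's name (e.g. `"VOI_01"`).
#' @return The updated `burden_result`.
#' @export
delete_voi <- function(result, voi_id) {
  nm <- vapply(result$vois, `[[`, "", "name")
  i <- match(voi_id, nm)
  if (is.na(i)) stop(sprintf("unknown VOI id '%s'", voi_id))
  result$vois <- result$vois[-i]
  result$statistics <- result$statistics[-i]
  result$deleted_ids <- c(result$deleted_ids, voi_id)
  result
}

#' Aggregated global mask of a burden result
#' @param result a `burden_result`.
#' @return A [voi_mask()] (empty mask when no VOIs remain).
#' @export
global_mask <- function(result) {
  if (!length(result$vois))
    return(voi_mask(array(FALSE, result$pet_geometry$dims),
                    result$pet_geometry, "total_tumor_burden"))
  aggregate_vois(result$vois, "total_tumor_burden")
}

#' Tabulate a burden result for CSV export
#'
#' One row per VOI plus a TOTAL row over the aggregate: total metabolic
#' volume is the summed VOI volume and total lesion glycolysis the sum of
#' mean SUV times volume.
#'
#' @param result a `burden_result`.
#' @param pet the [image_volume()] the result came from.
#' @return A data.frame with columns name, volume_ml, total, mean, min, max,
#'   peak, sd, tlg.
#' @export
burden_report <- function(result, pet) {
  row_of <- function(s) data.frame(
    name = s$name, volume_ml = s$volume_ml, total = s$total, mean = s$mean,
    min = s$min, max = s$max, peak = s$peak, sd = s$sd,
    tlg = if (is.na(s$tlg)) NA_real_ else s$tlg,
    stringsAsFactors = FALSE)
  rows <- lapply(result$statistics, row_of)
  if (length(result$vois)) {
    tot <- compute_statistics(pet, global_mask(result))
    tot$name <- "TOTAL"
    tot$tlg <- sum(vapply(result$statistics, function(s)
      if (is.na(s$tlg)) 0 else s$tlg, numeric(1)))
    rows <- c(rows, list(row_of(tot)))
  } else {
    rows <- list(data.frame(name = "TOTAL", volume_ml = 0, total = 0, mean = 0,
                            min = 0, max = 0, peak = 0, sd = 0, tlg = 0,
                            stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read / write a burden configuration as a key = value file
#' @param path file path.
#' @param cfg a [burden_config()].
#' @export
read_burden_config <- function(path) {
  ln <- grep("=", readLines(path), value = TRUE)
  kv <- lapply(strsplit(ln, "="), trimws)
  vals <- stats::setNames(lapply(kv, function(p) p[2]),
                          vapply(kv, `[`, "", 1))
  num <- function(k, d) if (!is.null(vals[[k]])) as.numeric(vals[[k]]) else d
  burden_config(
    grow_percent = num("grow_percent", 0.10),
    local_percent = num("local_percent", 0.42),
    secondary_peak_percent = num("secondary_peak_percent", 0.20),
    min_volume_ml = num("min_volume_ml", 0.3),
    mode = if (!is.null(vals$mode)) vals$mode else "percent",
    absolute_suv = if (!is.null(vals$absolute_suv)) as.numeric(vals$absolute_suv))
}

#' @rdname read_burden_config
#' @export
write_burden_config <- function(cfg, path) {
  ln <- c(paste("grow_percent =", cfg$grow_percent),
          paste("local_percent =", cfg$local_percent),
          paste("secondary_peak_percent =", cfg$secondary_peak_percent),
          paste("min_volume_ml =", cfg$min_volume_ml),
          paste("mode =", cfg$mode))
  if (!is.null(cfg$absolute_suv))
    ln <- c(ln, paste("absolute_suv =", cfg$absolute_suv))
  writeLines(ln, path)
  invisible(path)
}
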