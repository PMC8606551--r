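# Concentric ischemic layers, electrophysiological grading across layers,
# and the layer-peeling augmentation operator.

# tissue-grid neighbor offsets (face adjacency) as linear-index shifts
.grid_neighbors <- function(geom, idx) {
  d <- geom$dims
  nx <- d[["nx"]]; ny <- d[["ny"]]
  n <- prod(d)
  i <- ((idx - 1) %% nx) + 1
  j <- (((idx - 1) %/% nx) %% ny) + 1
  out <- list()
  out$xm <- ifelse(i > 1, idx - 1, NA)
  out$xp <- ifelse(i < nx, idx + 1, NA)
  out$ym <- ifelse(j > 1, idx - nx, NA)
  out$yp <- ifelse(j < ny, idx + nx, NA)
  if (length(d) == 3) {
    nz <- d[["nz"]]
    k <- ((idx - 1) %/% (nx * ny)) + 1
    out$zm <- ifelse(k > 1, idx - nx * ny, NA)
    out$zp <- ifelse(k < nz, idx + nx * ny, NA)
  }
  out
}

#' Assign concentric ischemic layers by boundary distance
#'
#' Every ischemic element receives a layer index 1 (outermost) to `L`
#' (innermost) by binning its distance to the outer surface of the ischemic
#' region (the nearest healthy-tissue element adjacent to ischemia) into `L`
#' bins. Equal-width distance bins are the default, matching the
#' distance-from-surface semantics of a gradually worsening border zone;
#' equal-volume bins are available as an option.
#'
#' @param geom a `ventricle_geometry` with a nonempty ischemic subdomain
#'   (any `region_label > 0` is treated as ischemic).
#' @param L requested layer count (reduced with a warning when the region
#'   has fewer distinct distance levels).
#' @param binning `"width"` (equal-width distance bins) or `"volume"`
#'   (equal element counts per layer).
#' @return List with `geometry` (layer indices written into
#'   `region_label`) and `layers`, a `layered_ischemia` object carrying
#'   per-element `layer_index`, `boundary_distance` (mm) and `L`.
#' @export
assign_layers <- function(geom, L, binning = c("width", "volume")) {
  stopifnot(inherits(geom, "ventricle_geometry"), L >= 1)
  binning <- match.arg(binning)
  isch <- which(geom$mask & geom$region_label > 0)
  if (length(isch) == 0) stop("geometry has no ischemic subdomain")
  L <- as.integer(L)
  healthy <- geom$mask & geom$region_label == 0
  nb <- .grid_neighbors(geom, isch)
  # healthy tissue elements adjacent to the ischemic region (the outer rim)
  rim <- unique(unlist(lapply(nb, function(v) {
    v <- v[!is.na(v)]
    v[healthy[v]]
  })))
  if (length(rim) == 0) {
    # region touches no healthy tissue (fills the domain): use domain edge
    dist <- rep(0, length(isch))
  } else {
    pc <- geom$centers[isch, , drop = FALSE]
    rc <- geom$centers[rim, , drop = FALSE]
    # min Euclidean distance to the rim, blockwise to bound memory
    dist <- vapply(seq_len(nrow(pc)), function(q) {
      sqrt(min(colSums((t(rc) - pc[q, ])^2)))
    }, numeric(1))
  }
  n_lev <- length(unique(round(dist, 9)))
  if (L > n_lev) {
    warning(sprintf("L = %d exceeds %d distinct distance levels; using L = %d",
                    L, n_lev, n_lev))
    L <- n_lev
  }
  if (binning == "width") {
    dmax <- max(dist)
    if (dmax == 0) layer <- rep(1L, length(dist))
    else layer <- pmin(L, floor(dist / dmax * L) + 1L)
  } else {
    qs <- quantile(dist, probs = seq_len(L - 1) / L, type = 1)
    layer <- as.integer(cut(dist, c(-Inf, qs, Inf), labels = FALSE))
  }
  # guarantee no empty layers (monotone re-map of used indices)
  used <- sort(unique(layer))
  layer <- match(layer, used)
  L <- length(used)
  geom$region_label[isch] <- layer
  layers <- structure(list(element = isch, layer_index = as.integer(layer),
                           boundary_distance = dist, L = L,
                           binning = binning),
                      class = "layered_ischemia")
  list(geometry = geom, layers = layers)
}

#' @export
print.layered_ischemia <- function(x, ...) {
  cat(sprintf("layered_ischemia: %d elements in %d layers (%s bins)\n",
              length(x$element), x$L, x$binning))
  print(table(layer = x$layer_index))
  invisible(x)
}

#' Electrophysiological grading configuration
#'
#' Defaults encode graded ischemic remodeling: extracellular potassium
#' rising linearly from 7.5 mM (outermost layer) to 10 mM (innermost);
#' I_Na and I_CaL reduced by 20% over the outer half of the layers and by
#' 30% over the inner half; a uniform open-fraction of ATP-sensitive K+
#' channels f_ATP = 0.0049; and a uniform 40% conductivity reduction over
#' all ischemic tissue.
#'
#' @param K_o_outer,K_o_inner extracellular potassium endpoints, mM.
#' @param inner_zone_fraction fraction of layers counted as the inner zone.
#' @param inner_current_reduction,outer_current_reduction fractional I_Na /
#'   I_CaL conductance reductions in the inner and outer zones.
#' @param f_atp open fraction of ATP-sensitive K+ channels.
#' @param conductivity_reduction fractional tissue conductivity reduction.
#' @return A `grading_config` object.
#' @export
grading_config <- function(K_o_outer = 7.5, K_o_inner = 10,
                           inner_zone_fraction = 0.5,
                           inner_current_reduction = 0.30,
                           outer_current_reduction = 0.20,
                           f_atp = 0.0049, conductivity_reduction = 0.40) {
  stopifnot(K_o_inner >= K_o_outer,
            inner_zone_fraction >= 0, inner_zone_fraction <= 1,
            inner_current_reduction >= 0, inner_current_reduction <= 1,
            outer_current_reduction >= 0, outer_current_reduction <= 1,
            f_atp >= 0, f_atp <= 1,
            conductivity_reduction >= 0, conductivity_reduction <= 1)
  structure(list(K_o_outer = K_o_outer, K_o_inner = K_o_inner,
                 inner_zone_fraction = inner_zone_fraction,
                 inner_current_reduction = inner_current_reduction,
                 outer_current_reduction = outer_current_reduction,
                 f_atp = f_atp,
                 conductivity_reduction = conductivity_reduction),
            class = "grading_config")
}

#' Per-layer electrophysiological parameter table
#'
#' Applies the grading law over `L` concentric layers: K_o interpolates
#' linearly between the configured endpoints (a single layer takes the
#' innermost value); layers beyond the outer zone (`k > floor(L * (1 -
#' inner_zone_fraction))`, ties to inner) take the inner current reduction;
#' f_ATP and the conductivity scale are uniform over all ischemic layers.
#'
#' @param layers a `layered_ischemia`, or an integer layer count.
#' @param cfg a [grading_config()].
#' @return Data frame with one row per layer: `layer`, `K_o`, `ina_scale`,
#'   `ical_scale`, `f_atp`, `cond_scale`.
#' @export
grade_layers <- function(layers, cfg = grading_config()) {
  L <- if (inherits(layers, "layered_ischemia")) layers$L
       else as.integer(layers)
  stopifnot(L >= 1)
  k <- seq_len(L)
  K_o <- if (L == 1) cfg$K_o_inner
         else cfg$K_o_outer + (k - 1) / (L - 1) * (cfg$K_o_inner - cfg$K_o_outer)
  n_outer <- floor(L * (1 - cfg$inner_zone_fraction))
  red <- ifelse(k > n_outer, cfg$inner_current_reduction,
                cfg$outer_current_reduction)
  data.frame(layer = k, K_o = K_o, ina_scale = 1 - red, ical_scale = 1 - red,
             f_atp = cfg$f_atp, cond_scale = 1 - cfg$conductivity_reduction)
}

#' Peel outer ischemic layers
#'
#' Relabels the outermost `k` layers as healthy tissue and re-indexes the
#' remaining layers 1..L-k, so that re-applying [grade_layers()] regenerates
#' a full normal-to-severe gradient over the smaller region (the border zone
#' regenerates). A model peeled by `k >= L` retains no ischemic tissue and
#' is flagged invalid.
#'
#' @param geom a `ventricle_geometry` with assigned layers.
#' @param layers the matching `layered_ischemia`.
#' @param k number of outer layers to remove (>= 0).
#' @return List `geometry`, `layers` (NULL when invalid), `valid`.
#' @export
peel_layers <- function(geom, layers, k) {
  if (k < 0) stop("k must be >= 0")
  k <- as.integer(k)
  if (k == 0) return(list(geometry = geom, layers = layers, valid = TRUE))
  L <- layers$L
  if (k >= L) {
    geom$region_label[layers$element] <- 0L
    geom$meta$peel <- (geom$meta$peel %||% 0L) + k
    return(list(geometry = geom, layers = NULL, valid = FALSE))
  }
  drop <- layers$layer_index <= k
  geom$region_label[layers$element[drop]] <- 0L
  keep <- !drop
  new_layers <- structure(list(element = layers$element[keep],
                               layer_index = layers$layer_index[keep] - k,
                               boundary_distance =
                                 layers$boundary_distance[keep],
                               L = L - k, binning = layers$binning),
                          class = "layered_ischemia")
  geom$region_label[new_layers$element] <- new_layers$layer_index
  geom$meta$peel <- (geom$meta$peel %||% 0L) + k
  list(geometry = geom, layers = new_layers, valid = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a peel-augmented model population
#'
#' Each baseline model contributes itself (peel 0) plus one variant per
#' peel level; variants whose peel removes all ischemic layers are excluded.
#'
#' @param baseline list of entries, each a list with `geometry` and
#'   `layers` (as returned by [assign_layers()]), optionally `id`.
#' @param peel_set integer peel levels.
#' @return A `model_population`: list with `models` (each carrying
#'   `geometry`, `layers`, `patient`, `peel`) and `manifest` data frame
#'   (`model_id`, `patient`, `peel`, `n_layers`, `ischemic_pct`,
#'   `excluded` counts in attributes).
#' @export
build_augmented_population <- function(baseline, peel_set = c(1, 2, 5, 10)) {
  stopifnot(length(baseline) > 0)
  models <- list()
  rows <- list()
  excluded <- 0L
  for (b in seq_along(baseline)) {
    pid <- baseline[[b]]$id %||% b
    for (k in c(0, sort(peel_set))) {
      if (k == 0) {
        g <- baseline[[b]]$geometry; ly <- baseline[[b]]$layers
        ok <- TRUE
      } else {
        p <- peel_layers(baseline[[b]]$geometry, baseline[[b]]$layers, k)
        g <- p$geometry; ly <- p$layers; ok <- p$valid
      }
      if (!ok) { excluded <- excluded + 1L; next }
      mid <- sprintf("%s_peel%d", pid, k)
      vols <- geometry_volumes(g)
      models[[mid]] <- list(geometry = g, layers = ly, patient = pid,
                            peel = k)
      rows[[mid]] <- data.frame(model_id = mid, patient = as.character(pid),
                                peel = k, n_layers = ly$L,
                                ischemic_pct =
                                  100 * vols["ischemic"] / vols["total"],
                                row.names = NULL)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(manifest, "excluded") <- excluded
  structure(list(models = models, manifest = manifest),
            class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat(sprintf("model_population: %d models from %d patients (%d excluded)\n",
              nrow(x$manifest), length(unique(x$manifest$patient)),
              attr(x$manifest, "excluded")))
  tab <- table(peel = x$manifest$peel)
  print(tab)
  invisible(x)
}
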