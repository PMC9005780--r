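#' Image similarity score (correlation distance)
#'
#' `d_img = 1 - r`, the Pearson correlation distance between the data and
#' simulated pixel heights, evaluated only at data pixels whose height lies
#' strictly above the estimated fibril axis height (the most reliable region,
#' least affected by tip-sample convolution). The simulated image is brought
#' onto the data's lateral frame and common row range first.
#'
#' @param data reference [height_map()] (straightened fibril).
#' @param sim simulated [height_map()], same pixel size, already
#'   periodicity-optimized ([optimize_periodicity()]).
#' @param axis_height_nm mask threshold: the fibril axis height, nm; default
#'   the data's stored `axis_height_nm`.
#' @return `d_img` in [0, 2].
#' @export
image_distance <- function(data, sim, axis_height_nm = data$axis_height_nm) {
  stopifnot(inherits(data, "height_map"), inherits(sim, "height_map"))
  if (is.null(axis_height_nm)) stop("axis_height_nm required")
  if (ncol(sim$heights) != ncol(data$heights))
    sim <- match_lateral_frame(sim, data)
  ny <- min(nrow(sim$heights), nrow(data$heights))
  D <- data$heights[seq_len(ny), , drop = FALSE]
  S <- sim$heights[seq_len(ny), , drop = FALSE]
  mask <- D > axis_height_nm
  if (sum(mask) < 3L) stop("undefined score: empty mask above the axis height")
  dv <- D[mask]; sv <- S[mask]
  if (stats::sd(dv) == 0 || stats::sd(sv) == 0)
    stop("undefined score: zero variance over the mask")
  1 - stats::cor(dv, sv)
}

#' Normalized morphometric parameter distance
#'
#' `d_par = |par_candidate - par_reference| / norm_max`, the absolute
#' difference normalized by the observed maximum absolute difference across
#' the candidate panel (or the theoretical maximum of 2 for handedness).
#'
#' @param value_candidate,value_reference parameter values.
#' @param norm_max normalization constant (> 0). If 0 (all candidates
#'   identical for this parameter) the distance is defined as 0, with a
#'   warning.
#' @return `d_par` in [0, 1].
#' @export
param_distance <- function(value_candidate, value_reference, norm_max) {
  if (norm_max < 0) stop("norm_max must be non-negative")
  if (norm_max == 0) {
    warning("norm_max is 0 (all candidates identical); distance defined as 0")
    return(rep(0, length(value_candidate)))
  }
  abs(value_candidate - value_reference) / norm_max
}

#' Combined similarity score
#'
#' The plain sum of the six component scores
#' `d_img + d_sym + d_hnd + d_cod + d_csa + d_csd`; lower values indicate
#' higher structural similarity.
#'
#' @param components numeric vector of the six scores (named or positional:
#'   d_img, d_sym, d_hnd, d_cod, d_csa, d_csd), all finite and >= 0.
#' @return `d_sum`.
#' @export
combined_score <- function(components) {
  comp_names <- c("d_img", "d_sym", "d_hnd", "d_cod", "d_csa", "d_csd")
  if (!is.null(names(components))) {
    if (!all(comp_names %in% names(components)))
      stop("missing component(s): ",
           paste(setdiff(comp_names, names(components)), collapse = ", "))
    components <- unlist(components)[comp_names]
  }
  components <- as.numeric(components)
  if (length(components) != 6L || any(!is.finite(components)))
    stop("exactly six finite components required; no silent imputation")
  if (any(components < 0)) stop("component scores must be >= 0")
  sum(components)
}

#' Analyze a straightened fibril image into a reference bundle
#'
#' Runs the full single-fibril pipeline: cross-over distance from the
#' centre-line profile, symmetry detection, 3D envelope reconstruction, and
#' the tip-accessible envelope cross-section (so AFM- and map-derived
#' cross-sections are directly comparable). The result is the reference
#' against which candidate structures are ranked.
#'
#' @param straight_img straightened, flattened [height_map()].
#' @param tip the imaging [build_tip()] model.
#' @param handedness fibril twist handedness (from the raw image), +1/-1.
#' @param sym_candidates candidate symmetry orders for [detect_symmetry()].
#' @return list with `image`, `envelope`, `cross_section`, `cod_nm`,
#'   `symmetry_order`, `handedness`, `csa_nm2`, `symmetry_scores`.
#' @export
analyze_fibril_image <- function(straight_img, tip, handedness = -1,
                                 sym_candidates = c(1L, 2L)) {
  prof <- centerline_profile(straight_img)
  cod <- crossover_distance(prof)$cod_nm
  sym <- detect_symmetry(straight_img, tip, cod, sym_candidates, handedness)
  env <- reconstruct_envelope(straight_img, tip, as.integer(sym), cod, handedness)
  cs_env <- envelope_cross_section(env)
  cs_tip <- tip_accessible_boundary(cs_env$curve, tip$radius_nm)
  straight_img$axis_height_nm <- env$axis_height_nm
  list(image = straight_img, envelope = env, cross_section = cs_tip,
       cod_nm = cod, symmetry_order = as.integer(sym),
       handedness = handedness, csa_nm2 = cross_section_area(cs_tip),
       symmetry_scores = attr(sym, "scores"))
}

# per-candidate pipeline: simulated image distance + morphometrics
candidate_metrics <- function(entry, reference, tip, pixel_size_nm,
                              target_length_nm) {
  surf <- entry$surface
  helical <- if (!is.null(entry$helical)) entry$helical else surf$helical
  if (is.null(surf)) {
    if (is.null(entry$volume)) stop("candidate needs a surface or a volume")
    surf <- align_long_axis(denoise_surface(extract_isosurface(entry$volume)))
    pose <- fit_screw_axis(surf, helical)
    surf <- pose$surface
  }
  if (diff(range(surf$vertices[, 3])) < target_length_nm)
    surf <- extend_helical(surf, helical, target_length_nm)
  sim <- simulate_topograph(surf, tip, pixel_size_nm)
  per <- optimize_periodicity(sim, reference$image)
  d_img <- image_distance(reference$image, per$image,
                          reference$envelope$axis_height_nm)
  csx <- entry$cross_section  # optionally precomputed (e.g. across repeats)
  if (is.null(csx)) {
    pts <- untwist_to_plane(surf, helical)
    csx <- tip_accessible_boundary(pts, tip$radius_nm)
  }
  list(d_img = d_img, sym = helical$symmetry_order, hnd = helical$handedness,
       cod_nm = helical_cod(helical), csa_nm2 = cross_section_area(csx),
       csd_nm2 = cross_section_difference(csx, reference$cross_section),
       periodicity_scale = per$scale, correlation = per$correlation)
}

#' Rank candidate structures against a reference AFM fibril
#'
#' For every candidate the full comparison pipeline is run: topograph
#' simulation at the reference pixel size, periodicity optimization, image
#' correlation distance, and the morphometric set (symmetry, handedness,
#' cross-over distance, tip-accessible cross-sectional area and
#' symmetric-difference area vs. the reference envelope cross-section).
#' Morphometric distances are normalized by their observed maxima across the
#' candidate panel (theoretical maximum 2 for handedness), summed with
#' `d_img`, and candidates are ranked ascending by the combined score
#' (ties break by `d_img`, then label).
#'
#' @param reference a bundle from [analyze_fibril_image()] (or the same
#'   structure assembled manually).
#' @param candidates list of entries, each with `label`, a `surface`
#'   ([surface_cloud()], screw axis = z) or `volume` ([volume_grid()]), and
#'   `helical` ([helical_params()]). An entry may carry a precomputed
#'   tip-accessible `cross_section` to avoid recomputation across repeated
#'   rankings.
#' @param tip the [build_tip()] model (must match the reference estimate).
#' @param target_length_factor candidates shorter than this multiple of the
#'   reference image length are helically extended first (default 1.1).
#' @return a `similarity_report`: `table` (one row per candidate, component
#'   scores, `d_sum`, `rank`), `norm_max`, `excluded` (failed candidates and
#'   reasons), `reference` summary.
#' @export
rank_candidates <- function(reference, candidates, tip,
                            target_length_factor = 1.1) {
  if (length(candidates) < 2L) stop("need at least 2 candidates")
  labels <- vapply(seq_along(candidates), function(i) {
    if (!is.null(candidates[[i]]$label)) candidates[[i]]$label
    else sprintf("candidate-%02d", i)
  }, character(1))
  px <- reference$image$pixel_size_nm
  target_len <- target_length_factor * (nrow(reference$image$heights) - 1L) * px
  metrics <- vector("list", length(candidates))
  excluded <- list()
  for (i in seq_along(candidates)) {
    m <- tryCatch(candidate_metrics(candidates[[i]], reference, tip, px,
                                    target_len),
                  error = function(e) e)
    if (inherits(m, "error")) {
      excluded[[labels[i]]] <- conditionMessage(m)
      message("candidate '", labels[i], "' excluded: ", conditionMessage(m))
    } else metrics[[i]] <- m
  }
  ok <- !vapply(metrics, is.null, logical(1))
  if (sum(ok) < 2L) stop("fewer than 2 candidates completed the pipeline")
  metrics <- metrics[ok]
  labels <- labels[ok]
  g <- function(f) vapply(metrics, function(m) as.numeric(m[[f]]), numeric(1))
  dsym_raw <- abs(g("sym") - reference$symmetry_order)
  dhnd_raw <- abs(g("hnd") - reference$handedness)
  dcod_raw <- abs(g("cod_nm") - reference$cod_nm)
  dcsa_raw <- abs(g("csa_nm2") - reference$csa_nm2)
  dcsd_raw <- g("csd_nm2")
  norm <- c(sym = max(dsym_raw), hnd = 2, cod = max(dcod_raw),
            csa = max(dcsa_raw), csd = max(dcsd_raw))
  nz <- function(x, nm) if (nm == 0) rep(0, length(x)) else x / nm
  tab <- data.frame(label = labels,
                    d_img = g("d_img"),
                    d_sym = nz(dsym_raw, norm["sym"]),
                    d_hnd = dhnd_raw / 2,
                    d_cod = nz(dcod_raw, norm["cod"]),
                    d_csa = nz(dcsa_raw, norm["csa"]),
                    d_csd = nz(dcsd_raw, norm["csd"]),
                    sym = g("sym"), hnd = g("hnd"), cod_nm = g("cod_nm"),
                    csa_nm2 = g("csa_nm2"), csd_nm2 = g("csd_nm2"),
                    periodicity_scale = g("periodicity_scale"),
                    stringsAsFactors = FALSE)
  tab$d_sum <- tab$d_img + tab$d_sym + tab$d_hnd + tab$d_cod + tab$d_csa +
    tab$d_csd
  ord <- order(tab$d_sum, tab$d_img, tab$label)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, norm_max = norm, excluded = excluded,
                 reference = list(cod_nm = reference$cod_nm,
                                  symmetry_order = reference$symmetry_order,
                                  handedness = reference$handedness,
                                  csa_nm2 = reference$csa_nm2)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Similarity ranking (lower d_sum = more similar):\n")
  print(format(x$table[, c("rank", "label", "d_img", "d_sym", "d_hnd",
                           "d_cod", "d_csa", "d_csd", "d_sum")],
               digits = 3), row.names = FALSE)
  if (length(x$excluded)) {
    cat("Excluded candidates:\n")
    for (nm in names(x$excluded)) cat("  ", nm, ": ", x$excluded[[nm]], "\n",
                                      sep = "")
  }
  invisible(x)
}

#' Write a similarity report as TSV + JSON
#' @param report a `similarity_report`.
#' @param path_prefix writes `<prefix>.tsv` (score table) and `<prefix>.json`
#'   (table, normalization constants, exclusions, reference parameters).
#' @return `path_prefix`, invisibly.
#' @export
write_similarity_report <- function(report, path_prefix) {
  utils::write.table(report$table, paste0(path_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(table = report$table,
                            norm_max = as.list(report$norm_max),
                            excluded = report$excluded,
                            reference = report$reference),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path_prefix)
}
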