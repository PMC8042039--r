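#' Pipeline run configuration
#'
#' Collects the file paths and flags of an end-to-end run. Either supply the
#' input objects directly to [run_pipeline()] or a config (list or YAML file)
#' naming the files.
#'
#' @param landmarks path to a wide landmark CSV (see [read_landmark_csv()]).
#' @param scheme path to a scheme YAML (see [read_scheme()]).
#' @param climate path to a climate CSV (see [read_climate_csv()]).
#' @param distances optional path to a square distance CSV; great-circle
#'   distances are used when omitted.
#' @param output_dir directory for result files (created if absent).
#' @param fossil_ids group ids treated as out-of-sample fossils: excluded
#'   from the consensus, group means and the fit; imputed against and
#'   aligned to the modern consensus, then projected post hoc.
#' @param sex_correction correct shapes and centroid sizes for sex
#'   dimorphism (fossils are treated as male).
#' @param weighted_centering GLS-weighted centering in the regression.
#' @param ridge diagonal ridge for the weight matrix.
#' @param gpa_tol,gpa_max_iter Procrustes convergence controls.
#' @param k_max adaptive-space dimensions to report.
#' @param max_missing missing-landmark exclusion threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(landmarks, scheme, climate, distances = NULL,
                       output_dir = "results", fossil_ids = character(),
                       sex_correction = TRUE, weighted_centering = FALSE,
                       ridge = 1e-8, gpa_tol = 1e-10, gpa_max_iter = 100L,
                       k_max = 2L, max_missing = 4L) {
  structure(list(landmarks = landmarks, scheme = scheme, climate = climate,
                 distances = distances, output_dir = output_dir,
                 fossil_ids = fossil_ids, sex_correction = sex_correction,
                 weighted_centering = weighted_centering, ridge = ridge,
                 gpa_tol = gpa_tol, gpa_max_iter = gpa_max_iter,
                 k_max = k_max, max_missing = max_missing),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields above.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full climate-shape analysis pipeline
#'
#' Executes, with logging: exclusion of specimens missing more than
#' `max_missing` landmarks; thin-plate-spline imputation of the remainder
#' (reference = sample consensus, re-estimated once); joint-GPA
#' symmetrization; sex-dimorphism correction of shapes and centroid sizes;
#' group mean shapes; climate standardization; geographic distances and the
#' similarity weight matrix; the weighted reduced rank regression with its
#' dimension shares and generalized R-squared; adaptive-space scores for all
#' specimens, group means and fossils; and the per-region size tables sorted
#' ascending by group median. Result files are written under
#' `config$output_dir`; on a stage error, partial outputs of this run are
#' removed and the error is re-signalled with the stage name.
#'
#' @param config a [run_config()] (or path to its YAML form).
#' @return (invisibly) a result bundle: `model`, `scores`, `sizes`,
#'   `size_summary`, `shares`, `r_squared`, `consensus`, `aligned`,
#'   `exclusions`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  written <- character()
  current_stage <- "setup"
  stage <- function(name) { current_stage <<- name; message("[stage] ", name) }
  out <- tryCatch(
    run_pipeline_impl(config, stage, function(f) written <<- c(written, f)),
    error = function(e) {
      unlink(written)
      stop("stage ", current_stage, ": ", conditionMessage(e), call. = FALSE)
    })
  invisible(out)
}

run_pipeline_impl <- function(config, stage, register) {
  stage("read inputs")
  scheme <- read_scheme(config$scheme)
  configs <- read_landmark_csv(config$landmarks, scheme)
  climate <- read_climate_csv(config$climate)
  is_fossil <- vapply(configs, function(cf)
    cf$group_id %in% config$fossil_ids || cf$specimen_id %in% config$fossil_ids,
    logical(1))
  fossils <- configs[is_fossil]
  modern <- configs[!is_fossil]
  if (length(modern) < 2) stop("need at least 2 non-fossil specimens")
  message("  ", length(modern), " modern specimens, ", length(fossils),
          " fossils, ", nrow(climate), " climate rows")

  stage("missing-landmark exclusion")
  excl <- vapply(modern, is_excluded, logical(1),
                 max_missing = config$max_missing)
  exclusions <- data.frame(
    specimen_id = vapply(modern[excl], `[[`, "", "specimen_id"),
    n_missing = vapply(modern[excl], n_missing, 0L))
  for (i in which(excl))
    message("  excluded ", modern[[i]]$specimen_id, ": ",
            n_missing(modern[[i]]), " missing landmarks (> ",
            config$max_missing, ")")
  modern <- modern[!excl]

  stage("thin-plate-spline imputation")
  has_miss <- vapply(modern, function(cf) n_missing(cf) > 0, logical(1))
  if (any(has_miss)) {
    complete <- modern[!has_miss]
    if (length(complete) < 2)
      stop("fewer than 2 complete specimens to build an imputation reference")
    ref <- gpa_align(complete, tol = config$gpa_tol,
                     max_iter = config$gpa_max_iter)$consensus
    pass1 <- modern
    pass1[has_miss] <- lapply(modern[has_miss], impute_missing, reference = ref,
                              scheme = scheme, max_missing = config$max_missing)
    ref2 <- gpa_align(pass1, tol = config$gpa_tol,
                      max_iter = config$gpa_max_iter)$consensus
    modern[has_miss] <- lapply(modern[has_miss], impute_missing,
                               reference = ref2, scheme = scheme,
                               max_missing = config$max_missing)
    message("  imputed ", sum(has_miss), " specimens")
  }

  stage("symmetrizing superimposition")
  sym <- symmetrize(modern, scheme, tol = config$gpa_tol,
                    max_iter = config$gpa_max_iter)
  consensus <- attr(sym, "consensus")
  shapes <- t(vapply(sym, function(cf) flatten_coords(cf$coords),
                     numeric(3 * n_landmarks(scheme))))
  colnames(shapes) <- coordinate_labels(scheme)
  meta <- config_meta(modern)
  cs_full <- vapply(modern, function(cf) centroid_size(cf$coords), 0)

  stage("sex-dimorphism correction")
  sex_offsets <- NULL
  if (config$sex_correction) {
    known <- meta$sex != "unknown"
    grand <- colMeans(shapes[known, , drop = FALSE])
    sex_offsets <- lapply(split(seq_len(nrow(shapes))[known], meta$sex[known]),
                          function(ix) grand - colMeans(shapes[ix, , drop = FALSE]))
    cs_grand <- mean(cs_full[known])
    cs_offsets <- lapply(split(which(known), meta$sex[known]),
                         function(ix) cs_grand - mean(cs_full[ix]))
    shapes <- remove_group_nuisance(shapes, meta$sex)
    cs_full <- as.numeric(remove_group_nuisance(cs_full, meta$sex))
  }

  stage("group mean shapes")
  modern_climate <- climate[!climate$group_id %in% config$fossil_ids, ,
                            drop = FALSE]
  gm <- group_means(shapes, meta$group_id)
  missing_groups <- setdiff(modern_climate$group_id, rownames(gm))
  if (length(missing_groups))
    stop("climate rows without specimens: ",
         paste(missing_groups, collapse = ", "))
  orphans <- setdiff(rownames(gm), modern_climate$group_id)
  if (length(orphans))
    stop("specimens without climate rows: ",
         paste(orphans, collapse = ", "))
  gm <- gm[modern_climate$group_id, , drop = FALSE]

  stage("climate design and weights")
  zs <- zscore_columns(modern_climate[, climate_vars()])
  rownames(zs$X) <- modern_climate$group_id
  D <- if (!is.null(config$distances)) {
    Dm <- read_distance_csv(config$distances)
    Dm[modern_climate$group_id, modern_climate$group_id]
  } else haversine_matrix(modern_climate)
  W <- weights_from_distances(D)

  stage("weighted reduced rank regression")
  model <- fit_weighted_rrr(zs$X, gm, W, ridge = config$ridge,
                            weighted_centering = config$weighted_centering,
                            x_center = zs$means, x_scale = zs$sds)
  shares <- dimension_shares(model)
  r2 <- variance_explained(model)
  message(sprintf("  variance explained %.1f%%; shares %s", 100 * r2,
                  paste(sprintf("%.1f%%", 100 * shares), collapse = ", ")))

  stage("adaptive-space projection")
  k_max <- min(config$k_max, model$r)
  proj_fossil <- function(cf) {
    if (n_missing(cf) > 0)
      cf <- impute_missing(cf, consensus, scheme,
                           max_missing = config$max_missing)
    row <- symmetric_projection_row(cf, consensus, scheme)
    if (config$sex_correction) {
      sx <- if (cf$sex == "unknown") "M" else cf$sex  # fossils assumed male
      if (!is.null(sex_offsets[[sx]])) row <- row + sex_offsets[[sx]]
    }
    row
  }
  fossil_rows <- if (length(fossils))
    do.call(rbind, lapply(fossils, proj_fossil)) else NULL
  score_rows <- rbind(shapes, gm, fossil_rows)
  sc <- adaptive_scores(model, score_rows, k_max = k_max)
  scores <- data.frame(
    id = c(meta$specimen_id, rownames(gm),
           vapply(fossils, `[[`, "", "specimen_id")),
    group_id = c(meta$group_id, rownames(gm),
                 vapply(fossils, `[[`, "", "group_id")),
    type = c(rep("specimen", nrow(shapes)), rep("group_mean", nrow(gm)),
             rep("fossil", length(fossils))),
    sc, stringsAsFactors = FALSE)

  stage("centroid-size tables")
  fossil_complete <- lapply(fossils, function(cf)
    if (n_missing(cf) > 0)
      impute_missing(cf, consensus, scheme, max_missing = config$max_missing)
    else cf)
  all_cfg <- c(modern, fossil_complete)
  sizes <- do.call(rbind, lapply(seq_along(all_cfg), function(i) {
    cf <- all_cfg[[i]]
    rs <- region_sizes(cf, scheme)
    data.frame(specimen_id = cf$specimen_id, group_id = cf$group_id,
               sex = cf$sex, region = rs$region,
               absolute_cs = rs$absolute_cs, relative_cs = rs$relative_cs,
               full_cs = attr(rs, "full_cs"), stringsAsFactors = FALSE)
  }))
  if (config$sex_correction) {
    # corrected full CS for modern specimens (fossils pass through as male)
    corr <- stats::setNames(cs_full, meta$specimen_id)
    idx <- sizes$specimen_id %in% names(corr)
    sizes$full_cs_corrected <- sizes$full_cs
    sizes$full_cs_corrected[idx] <- corr[sizes$specimen_id[idx]]
    fidx <- !idx
    if (any(fidx))
      sizes$full_cs_corrected[fidx] <-
        sizes$full_cs[fidx] + (cs_offsets[["M"]] %||% 0)
  }
  size_summary <- report_sizes(sizes)

  stage("write outputs")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  wr <- function(df, f) {
    utils::write.csv(df, p(f), row.names = FALSE); register(p(f)); p(f)
  }
  files <- c(
    model = { write_rrr_model(model, p("model.yaml")); register(p("model.yaml")); p("model.yaml") },
    scores = wr(scores, "scores.csv"),
    climate_loadings = wr(data.frame(variable = model$x_labels,
                                     model$U, check.names = FALSE),
                          "climate_loadings.csv"),
    shape_loadings = wr(data.frame(coordinate = model$y_labels,
                                   model$V, check.names = FALSE),
                        "shape_loadings.csv"),
    sizes = wr(sizes, "sizes.csv"),
    size_summary = wr(size_summary, "size_summary.csv"),
    consensus = wr(data.frame(label = scheme$labels, consensus,
                              check.names = FALSE), "consensus.csv"),
    aligned = wr(data.frame(specimen_id = meta$specimen_id,
                            group_id = meta$group_id, shapes,
                            check.names = FALSE), "aligned_shapes.csv"))
  report <- c(
    sprintf("specimens analysed: %d (excluded: %d, fossils projected: %d)",
            nrow(shapes), nrow(exclusions), length(fossils)),
    sprintf("groups: %d; climate variables: %s", nrow(gm),
            paste(model$x_labels, collapse = ", ")),
    sprintf("variance explained (generalized R^2): %.2f%%", 100 * r2),
    sprintf("dimension shares: %s",
            paste(sprintf("%.2f%%", 100 * shares), collapse = ", ")))
  writeLines(report, p("report.txt")); register(p("report.txt"))
  files <- c(files, report = p("report.txt"))

  invisible(list(model = model, scores = scores, sizes = sizes,
                 size_summary = size_summary, shares = shares,
                 r_squared = r2, consensus = consensus, aligned = shapes,
                 exclusions = exclusions, files = files, scheme = scheme))
}

# align a single specimen and its reflected-relabeled copy to a fixed
# consensus and average: symmetric shape row for out-of-sample specimens
symmetric_projection_row <- function(config, consensus, scheme) {
  a <- align_new_specimen(config, consensus)
  b <- align_new_specimen(reflect_relabel(config, scheme), consensus)
  (a + b) / 2
}

#' Per-group centroid-size summaries, sorted ascending by median
#'
#' For every region and measure (absolute and relative centroid size),
#' summarises each group by its median and quartiles and orders groups by
#' ascending median, ties broken by group name — the ordering convention of
#' the size boxplots.
#'
#' @param sizes long table from [run_pipeline()] (columns `group_id`,
#'   `region`, `absolute_cs`, `relative_cs`).
#' @return data frame with `region`, `measure`, `group_id`, `median`, `q1`,
#'   `q3`, `n`, ordered within region and measure.
#' @export
report_sizes <- function(sizes) {
  if (!nrow(sizes)) stop("empty sizes table")
  blocks <- list(absolute = "absolute_cs", relative = "relative_cs")
  out <- do.call(rbind, lapply(names(blocks), function(ms) {
    col <- blocks[[ms]]
    do.call(rbind, lapply(unique(sizes$region), function(rg) {
      sub <- sizes[sizes$region == rg, ]
      sp <- split(sub[[col]], sub$group_id)
      df <- data.frame(region = rg, measure = ms, group_id = names(sp),
                       median = vapply(sp, stats::median, 0),
                       q1 = vapply(sp, function(v) unname(stats::quantile(v, 0.25)), 0),
                       q3 = vapply(sp, function(v) unname(stats::quantile(v, 0.75)), 0),
                       n = vapply(sp, length, 0L), stringsAsFactors = FALSE)
      df[order(df$median, df$group_id), ]
    }))
  }))
  rownames(out) <- NULL
  out
}
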