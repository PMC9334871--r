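# End-to-end validation workflow: titration -> optimal amounts ->
# self-blocking -> related-protein blocking / cross-reactivity ->
# per-cell-type expression map -> physiological contrast check ->
# antibody ranking. Configurable, seeded, and bit-identical on re-runs
# for fully synthetic inputs.

#' Run the antibody validation workflow
#'
#' Executes the configured stages in order for every antibody:
#' (1) synthetic titration and optimal-amount selection; (2) blocking
#' panel (self and related proteins) and specificity classification;
#' (3) per-cell-type expression map; (4) physiological two-condition
#' contrast; plus optional epitope-alignment and image-quantification
#' jobs. Emits a report bundle (list; JSON + CSV files when
#' \code{output_dir} is set) ending in the antibody ranking. All
#' thresholds and seeds are echoed into the report.
#'
#' @param config configuration list, or path to a YAML file. Required
#'   fields: \code{seed}; at least one stage. Per-antibody entries under
#'   \code{antibodies} may carry \code{titration} (\code{amounts},
#'   \code{reference}, \code{model} = bindingModel fields),
#'   \code{blocking} (\code{specific}, \code{background}, \code{cv},
#'   \code{kappa} map, \code{conditions} list) and \code{expression}
#'   (per cell type \code{ab_mean}, \code{iso_mean}, \code{cv}).
#'   Optional top-level: \code{n_events}, \code{gating}
#'   (\code{strategy}), \code{policy} (\code{theta},
#'   \code{iso_ratio_cap}), \code{thresholds} (\code{self},
#'   \code{cross}), \code{contrast}, \code{alignment}, \code{icc},
#'   \code{output_dir}.
#' @return report list: per-stage results, \code{ranking},
#'   \code{provenance}.
#' @export
runValidation <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    validateConfig(config)
    seed <- config$seed
    n_events <- config$n_events %||% 20000L
    hierarchy <- defaultHierarchy(config$gating$strategy %||% "scatter_only")
    theta <- config$policy$theta %||% 0.75
    iso_cap <- config$policy$iso_ratio_cap %||% Inf
    thr_self <- config$thresholds$self %||% 0.85
    thr_cross <- config$thresholds$cross %||% 0.40
    out_dir <- config$output_dir
    if (!is.null(out_dir) && !dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)

    report <- list(provenance = list(
        seed = seed, n_events = n_events, theta = theta,
        iso_ratio_cap = iso_cap, self_threshold = thr_self,
        cross_threshold = thr_cross,
        strategy = hierarchy@strategy,
        package_version = as.character(utils::packageVersion("flowAbVal"))))

    runStage <- function(stage, fn) {
        tryCatch(fn(), error = function(e) {
            stop(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), call. = FALSE)
        })
    }

    assessments <- list()
    titration_rows <- list()
    blocking_rows <- list()
    expr_rows <- list()
    ab_names <- vapply(config$antibodies %||% list(), `[[`, character(1L),
                       "name")

    for (k in seq_along(config$antibodies)) {
        ab <- config$antibodies[[k]]
        ab_seed <- seed + 1000L * k

        if (!is.null(ab$titration)) {
            res <- runStage(paste0("titration:", ab$name), function() {
                tc <- ab$titration
                model <- bindingModel(tc$model$Bmax, tc$model$Kd,
                                      tc$model$slope %||% 0,
                                      tc$model$background %||% 100,
                                      tc$model$cv %||% 0.5)
                gen <- generateTitrationSeries(model, tc$amounts, ab_seed,
                                               n_events, ab$name)
                stats <- do.call(rbind, lapply(gen$pairs, measureStainPair,
                                               hierarchy = hierarchy))
                series <- titrationSeries(ab$name, stats, tc$reference)
                tab <- evaluateTitration(series)
                list(table = tab,
                     optimal = selectOptimalAmount(series, theta, iso_cap))
            })
            titration_rows[[ab$name]] <- cbind(antibody = ab$name,
                                               res$table,
                                               optimal = res$optimal)
        }

        if (!is.null(ab$blocking)) {
            res <- runStage(paste0("blocking:", ab$name), function() {
                bc <- ab$blocking
                truth <- blockingTruth(unlist(bc$kappa), bc$h %||% 0)
                rows <- lapply(seq_along(bc$conditions), function(i) {
                    cn <- bc$conditions[[i]]
                    cond <- blockingCondition(cn$blocker, cn$fold %||% 600,
                                              cn$temperature %||% "RT",
                                              cn$duration %||% 2)
                    exp <- generateBlockingExperiment(
                        truth, cond, bc$specific,
                        bc$background %||% 100, bc$cv %||% 0.5,
                        n_events, ab_seed + 10L * i, ab$name)
                    meas <- measureBlocking(exp, hierarchy)
                    data.frame(blocker = cond$blocker, fold = cond$fold,
                               condition = paste0(cond$fold, "x_",
                                                  cond$temperature),
                               replicate = cn$replicate %||% 1L,
                               efficiency = as.numeric(meas$efficiency),
                               qc_flag = attr(meas$efficiency, "qc_flag"),
                               kappa_true = exp$truth$kappa_effective,
                               stringsAsFactors = FALSE)
                })
                do.call(rbind, rows)
            })
            blocking_rows[[ab$name]] <- cbind(antibody = ab$name, res)
            profile <- summarizeBlockingPanel(res, ab$name)
            assessments[[ab$name]] <-
                classifySpecificity(profile, thr_self, thr_cross)
        }

        if (!is.null(ab$expression)) {
            res <- runStage(paste0("expression:", ab$name), function() {
                si <- vapply(seq_along(ab$expression), function(i) {
                    ex <- ab$expression[[i]]
                    pair <- generateStainPair(
                        syntheticSampleSpec(ex$ab_mean, ex$cv %||% 0.5,
                                            n_events,
                                            cell_type = names(ab$expression)[i]),
                        syntheticSampleSpec(ex$iso_mean, ex$cv %||% 0.5,
                                            n_events, condition = "isotype",
                                            cell_type = names(ab$expression)[i]),
                        ab_seed + 100L + i)
                    measureStainPair(pair, hierarchy)$si
                }, numeric(1L))
                names(si) <- names(ab$expression)
                c(list(si = si), classifyExpression(si))
            })
            expr_rows[[ab$name]] <- data.frame(
                antibody = ab$name, cell_type = names(res$si),
                si = unname(res$si), class = unname(res$classes),
                stringsAsFactors = FALSE)
        }
    }

    if (length(titration_rows))
        report$titration <- do.call(rbind, unname(titration_rows))
    if (length(blocking_rows))
        report$blocking <- do.call(rbind, unname(blocking_rows))
    if (length(expr_rows))
        report$expression <- do.call(rbind, unname(expr_rows))
    if (length(assessments))
        report$ranking <- rankAntibodies(unname(assessments))

    if (!is.null(config$contrast)) {
        report$contrast <- runStage("contrast", function() {
            cn <- config$contrast
            rows <- lapply(names(cn$conditions), function(lab) {
                cc <- cn$conditions[[lab]]
                pair <- generateStainPair(
                    syntheticSampleSpec(cc$ab_mean, cc$cv %||% 0.5,
                                        n_events),
                    syntheticSampleSpec(cc$iso_mean, cc$cv %||% 0.5,
                                        n_events, condition = "isotype"),
                    seed + match(lab, names(cn$conditions)) * 7L)
                st <- measureStainPair(pair, hierarchy,
                                       form = cn$form %||% "ratio")
                cbind(condition = lab, st)
            })
            do.call(rbind, rows)
        })
    }

    if (!is.null(config$alignment)) {
        report$alignment <- runStage("alignment", function() {
            seqs <- referenceSequences()
            epis <- antibodyEpitopes()
            jobs <- config$alignment$epitopes %||% names(epis)
            targets <- config$alignment$targets %||%
                setdiff(names(seqs), "SYUA_HUMAN")
            epitopeCrossreactivityTable(
                as.character(seqs[["SYUA_HUMAN"]]), epis[jobs],
                setNames(as.character(seqs[targets]), targets),
                gapCost = config$alignment$gapCost %||% "open_plus_size")
        })
    }

    if (!is.null(config$icc)) {
        report$icc <- runStage("icc", function() {
            jobs <- config$icc$images
            res <- lapply(seq_along(jobs), function(i) {
                jb <- jobs[[i]]
                gen <- generateICCImage(
                    jb$width %||% 128L, jb$height %||% 128L,
                    shapes = jb$shapes,
                    marker_fg = jb$marker_fg %||% 200,
                    marker_bg = jb$marker_bg %||% 10,
                    target_in = jb$target_in, target_out = jb$target_out %||% 5,
                    noise_sd = jb$noise_sd %||% 0, seed = seed + i)
                q <- quantifyICC(gen$image)
                data.frame(image = names(jobs)[i] %||% i,
                           threshold = q$threshold,
                           mask_fraction = q$mask_fraction,
                           mean_gray = q$mean_gray,
                           target_in_true = gen$truth$target_in)
            })
            do.call(rbind, res)
        })
    }

    if (!is.null(out_dir)) {
        for (nm in intersect(names(report),
                             c("titration", "blocking", "expression",
                               "ranking", "contrast", "icc")))
            utils::write.csv(report[[nm]],
                             file.path(out_dir, paste0(nm, ".csv")),
                             row.names = FALSE)
        jsonlite::write_json(
            report[setdiff(names(report), "alignment")],
            file.path(out_dir, "report.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    report
}

# Config schema check: fails before any computation.
validateConfig <- function(config) {
    if (!is.list(config) || !length(config))
        abort("empty or non-list workflow configuration", "config_error")
    if (is.null(config$seed))
        abort("config requires a 'seed' (synthetic stages are seeded)",
              "config_error")
    stages <- c("antibodies", "contrast", "alignment", "icc")
    if (!any(stages %in% names(config)))
        abort(paste0("config defines no stage; need one of: ",
                     paste(stages, collapse = ", ")), "config_error")
    for (ab in config$antibodies %||% list()) {
        if (is.null(ab$name))
            abort("every antibody entry needs a 'name'", "config_error")
        if (!is.null(ab$titration)) {
            tc <- ab$titration
            if (is.null(tc$amounts) || is.null(tc$reference) ||
                is.null(tc$model$Bmax) || is.null(tc$model$Kd))
                abort(paste0("titration config for '", ab$name,
                             "' needs amounts, reference, model$Bmax, ",
                             "model$Kd"), "config_error")
        }
        if (!is.null(ab$blocking)) {
            bc <- ab$blocking
            if (is.null(bc$specific) || is.null(bc$kappa) ||
                is.null(bc$conditions))
                abort(paste0("blocking config for '", ab$name,
                             "' needs specific, kappa, conditions"),
                      "config_error")
        }
    }
    if (!is.null(config$icc) && is.null(config$icc$images))
        abort("icc config needs an 'images' list", "config_error")
    invisible(TRUE)
}
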