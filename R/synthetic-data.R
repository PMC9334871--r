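# Synthetic cytometry event tables, titration series, blocking
# experiments and two-channel images, with recorded ground truth for
# every recovery test.
#
# Statistical structure: fluorescence and viability-dye intensities are
# lognormal (standard for cytometry signals), scatter channels are
# normal truncated at zero. Every generator is a pure function of
# (spec, seed): the RNG is seeded locally and the caller's RNG state is
# untouched.

SYNTH_CHANNELS <- data.frame(
    name = c("FSC-A", "FSC-H", "FSC-Width", "SSC-A", "FL1", "VIA"),
    role = c("FSC-A", "FSC-H", "FSC-Width", "SSC-A", "fluorescence",
             "viability"),
    detector = c("FSC-A", "FSC-H", "FSC-Width", "SSC-A", "FL1-A", "FL4-A"),
    stringsAsFactors = FALSE)

# normal truncated at zero via inverse-CDF (exact, vectorised)
rtnorm0 <- function(n, mean, sd) {
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(runif(n, lo, 1), mean, sd)
}

rlnormGM <- function(n, gm, cv) {
    rlnorm(n, meanlog = log(gm), sdlog = sqrt(log1p(cv^2)))
}

#' Population specification for the synthetic event generator
#'
#' @param label one of \code{live_singlet}, \code{debris}, \code{dead},
#'   \code{doublet}.
#' @param fraction expected fraction of events (fractions over a sample
#'   must sum to 1).
#' @param fsc_h,fsc_w,ssc \code{c(mean, sd)} of the zero-truncated
#'   normal scatter channels.
#' @param fl \code{c(gm, cv)} of the lognormal fluorescence signal
#'   (geometric mean and arithmetic CV).
#' @param via \code{c(gm, cv)} of the viability dye (elevated for dead
#'   cells).
#' @return a \code{population_spec} list.
#' @export
populationSpec <- function(label, fraction, fsc_h, fsc_w, ssc, fl, via) {
    stopifnot(label %in% c("live_singlet", "debris", "dead", "doublet"),
              fraction >= 0,
              all(c(fsc_h[2L], fsc_w[2L], ssc[2L]) > 0),
              fl[1L] > 0, fl[2L] > 0, via[1L] > 0, via[2L] > 0)
    structure(list(label = label, fraction = fraction, fsc_h = fsc_h,
                   fsc_w = fsc_w, ssc = ssc, fl = fl, via = via),
              class = "population_spec")
}

#' Synthetic sample specification
#'
#' Describes one stained or control sample as a mixture of live
#' singlets, debris, dead cells and doublets, emulating the populations
#' visible on the gating scatter plots. Defaults give a clean
#' preparation: 70 percent live singlets, 10 percent each of debris,
#' dead cells and doublets, 20,000 acquired events, with debris and dead
#' cells separated from live cells by more than 6 SD on FSC-H and the
#' dead-cell dye signal 20-fold above live background.
#'
#' @param live_fl_mean arithmetic mean fluorescence of the live-singlet
#'   population (the quantity MFI estimates).
#' @param live_fl_cv arithmetic CV of that signal (default 0.5, a
#'   typical width for a stained unimodal population).
#' @param n_events number of acquired events (default 20000).
#' @param condition condition label (stained | isotype | no-stain |
#'   blocked:<protein>).
#' @param cell_type sample cell type annotation.
#' @param antibody,amount antibody annotation (name, microgram per 50
#'   microlitre).
#' @param fractions named fractions for live_singlet, debris, dead,
#'   doublet; must sum to 1.
#' @param background_fl_mean arithmetic mean fluorescence of
#'   non-live-singlet events (debris autofluorescence).
#' @return a \code{synthetic_sample_spec} list.
#' @export
syntheticSampleSpec <- function(live_fl_mean, live_fl_cv = 0.5,
                                n_events = 20000L, condition = "stained",
                                cell_type = "hiPSC",
                                antibody = NA_character_,
                                amount = NA_real_,
                                fractions = c(live_singlet = 0.7,
                                              debris = 0.1, dead = 0.1,
                                              doublet = 0.1),
                                background_fl_mean = 30) {
    if (abs(sum(fractions) - 1) > 1e-9)
        abort("population fractions must sum to 1", "spec_error")
    if (n_events < 1L) abort("n_events must be >= 1", "spec_error")
    if (live_fl_cv <= 0)
        abort("live_fl_cv must be > 0 (SD of the population would vanish)",
              "spec_error")
    gm_live <- live_fl_mean / sqrt(1 + live_fl_cv^2)
    gm_bg <- background_fl_mean / sqrt(1 + 0.6^2)
    pops <- list(
        populationSpec("live_singlet", fractions[["live_singlet"]],
                       fsc_h = c(110, 12), fsc_w = c(60, 8),
                       ssc = c(80, 15), fl = c(gm_live, live_fl_cv),
                       via = c(50, 0.3)),
        populationSpec("debris", fractions[["debris"]],
                       fsc_h = c(20, 4), fsc_w = c(40, 10),
                       ssc = c(20, 8), fl = c(gm_bg, 0.6),
                       via = c(50, 0.3)),
        populationSpec("dead", fractions[["dead"]],
                       fsc_h = c(30, 4), fsc_w = c(65, 8),
                       ssc = c(70, 15), fl = c(gm_live, live_fl_cv),
                       via = c(1000, 0.3)),
        populationSpec("doublet", fractions[["doublet"]],
                       fsc_h = c(110, 12), fsc_w = c(110, 10),
                       ssc = c(160, 20), fl = c(gm_live, live_fl_cv),
                       via = c(50, 0.3)))
    structure(list(populations = pops, n_events = as.integer(n_events),
                   condition = condition, cell_type = cell_type,
                   antibody = antibody, amount = amount,
                   live_fl_mean = live_fl_mean, live_fl_cv = live_fl_cv),
              class = "synthetic_sample_spec")
}

#' Generate a synthetic cytometry sample
#'
#' Events are drawn per population; doublets are synthesized as sums of
#' two live-singlet draws on the area channels with a singlet-like
#' height, so their pulse area-to-height ratio is about twice the
#' singlet ratio. Identical (spec, seed) pairs give identical tables.
#'
#' @param spec a \code{\link{syntheticSampleSpec}} (or a bare list with
#'   a \code{populations} element of \code{\link{populationSpec}}s).
#' @param seed RNG seed (mandatory).
#' @return list: \code{table} (an \linkS4class{EventTable}) and
#'   \code{truth} (per-event population labels, the generating spec, and
#'   the arithmetic mean/SD of the live-singlet fluorescence).
#' @export
generateSample <- function(spec, seed) {
    fr <- vapply(spec$populations, `[[`, numeric(1L), "fraction")
    if (abs(sum(fr) - 1) > 1e-9)
        abort("population fractions must sum to 1", "spec_error")
    n <- spec$n_events
    withSeed(seed, {
        labels <- sample(vapply(spec$populations, `[[`, character(1L),
                                "label"),
                         n, replace = TRUE, prob = fr)
        m <- matrix(0, n, nrow(SYNTH_CHANNELS),
                    dimnames = list(NULL, SYNTH_CHANNELS$name))
        live <- spec$populations[[which(vapply(spec$populations, `[[`,
                    character(1L), "label") == "live_singlet")[1L]]]
        for (p in spec$populations) {
            idx <- which(labels == p$label)
            k <- length(idx)
            if (!k) next
            if (p$label == "doublet") {
                h1 <- rtnorm0(k, live$fsc_h[1L], live$fsc_h[2L])
                h2 <- rtnorm0(k, live$fsc_h[1L], live$fsc_h[2L])
                r1 <- rnorm(k, 1, 0.04); r2 <- rnorm(k, 1, 0.04)
                m[idx, "FSC-H"] <- pmax(h1, h2)
                m[idx, "FSC-A"] <- h1 * r1 + h2 * r2
                m[idx, "SSC-A"] <- rtnorm0(k, p$ssc[1L], p$ssc[2L])
                m[idx, "FL1"] <- rlnormGM(k, p$fl[1L], p$fl[2L]) +
                    rlnormGM(k, p$fl[1L], p$fl[2L])
            } else {
                h <- rtnorm0(k, p$fsc_h[1L], p$fsc_h[2L])
                m[idx, "FSC-H"] <- h
                m[idx, "FSC-A"] <- h * rnorm(k, 1, 0.04)
                m[idx, "SSC-A"] <- rtnorm0(k, p$ssc[1L], p$ssc[2L])
                m[idx, "FL1"] <- rlnormGM(k, p$fl[1L], p$fl[2L])
            }
            m[idx, "FSC-Width"] <- rtnorm0(k, p$fsc_w[1L], p$fsc_w[2L])
            m[idx, "VIA"] <- rlnormGM(k, p$via[1L], p$via[2L])
        }
        m[m < 0] <- 0  # pulse areas cannot be negative
        meta <- list(sample_id = paste0("synth-", seed),
                     antibody = spec$antibody, amount = spec$amount,
                     condition = spec$condition,
                     cell_type = spec$cell_type, synthetic = TRUE,
                     seed = seed)
        truth <- list(labels = labels, spec = spec,
                      live_fl_mean = spec$live_fl_mean,
                      live_fl_sd = spec$live_fl_mean * spec$live_fl_cv)
        list(table = EventTable(m, SYNTH_CHANNELS, meta), truth = truth)
    })
}

#' Generate a stained/isotype sample pair with known stain index
#'
#' Both specs must share all populations except the fluorescence means.
#' The ground-truth stain index
#' \eqn{(\mu_{ab} - \mu_{iso}) / (2 \sigma_{iso})} is recorded from the
#' generating arithmetic moments.
#'
#' @param spec_ab,spec_iso \code{\link{syntheticSampleSpec}}s for the
#'   antibody-stained and isotype-control samples.
#' @param seed RNG seed; the two samples use derived sub-seeds.
#' @return list: \code{ab}, \code{iso} (each as from
#'   \code{\link{generateSample}}) and \code{truth} with \code{si_true},
#'   \code{mfi_ab_true}, \code{mfi_iso_true}, \code{sd_iso_true}.
#' @export
generateStainPair <- function(spec_ab, spec_iso, seed) {
    if (spec_iso$live_fl_cv <= 0 || spec_ab$live_fl_cv <= 0)
        abort("degenerate spec: fluorescence CV must be > 0", "spec_error")
    if (length(spec_ab$populations) != length(spec_iso$populations))
        abort("stain-pair specs must share their population structure",
              "spec_error")
    mu_ab <- spec_ab$live_fl_mean
    mu_iso <- spec_iso$live_fl_mean
    sd_iso <- mu_iso * spec_iso$live_fl_cv
    ab <- generateSample(spec_ab, seed)
    iso <- generateSample(spec_iso, seed + 1L)
    list(ab = ab, iso = iso,
         truth = list(si_true = (mu_ab - mu_iso) / (2 * sd_iso),
                      mfi_ab_true = mu_ab, mfi_iso_true = mu_iso,
                      sd_iso_true = sd_iso))
}

#' Gate a generated stain pair and compute its stain statistics
#'
#' Convenience bridge from generator output to the metrics layer: both
#' samples are gated through the same hierarchy and summarized with
#' \code{\link{stainStatistics}}.
#'
#' @param pair output of \code{\link{generateStainPair}}.
#' @param hierarchy a \linkS4class{GateHierarchy} (default
#'   \code{defaultHierarchy("scatter_only")}).
#' @param channel fluorescence channel (default \code{"FL1"}).
#' @param form normalized-MFI form.
#' @return one-row data.frame from \code{\link{stainStatistics}}.
#' @export
measureStainPair <- function(pair, hierarchy = defaultHierarchy(),
                             channel = "FL1", form = "ratio") {
    gab <- subsetEvents(pair$ab$table,
                        applyHierarchy(pair$ab$table, hierarchy))
    gis <- subsetEvents(pair$iso$table,
                        applyHierarchy(pair$iso$table, hierarchy))
    stainStatistics(gab, gis, channel = channel,
                    amount = sampleMeta(pair$ab$table)$amount %||% NA_real_,
                    form = form)
}

#' Saturation-binding model for titration series
#'
#' Antibody signal: \code{background + Bmax * c / (Kd + c) + slope * c};
#' isotype signal: \code{background + slope * c}. The specific component
#' saturates with amount c while nonspecific binding grows linearly and
#' applies to antibody and isotype alike.
#'
#' @param Bmax saturating specific signal.
#' @param Kd half-saturation amount (microgram, > 0).
#' @param slope nonspecific signal per microgram.
#' @param background background MFI.
#' @param cv arithmetic CV of each generated population.
#' @return a \code{binding_model} list.
#' @export
bindingModel <- function(Bmax, Kd, slope = 0, background = 100, cv = 0.5) {
    stopifnot(Bmax >= 0, Kd > 0, slope >= 0, background >= 0, cv > 0)
    structure(list(Bmax = Bmax, Kd = Kd, slope = slope,
                   background = background, cv = cv),
              class = "binding_model")
}

#' Generate a synthetic titration series
#'
#' One stained/isotype pair per amount under a
#' \code{\link{bindingModel}}; ground truth records the model MFIs and
#' the implied true stain index at each amount.
#'
#' @param model a \code{\link{bindingModel}}.
#' @param amounts tested amounts (microgram per staining, > 0).
#' @param seed RNG seed.
#' @param n_events events per sample.
#' @param antibody antibody label.
#' @return list: \code{pairs} (per amount, from
#'   \code{\link{generateStainPair}}), \code{truth} data.frame
#'   (\code{amount}, \code{mfi_ab_true}, \code{mfi_iso_true},
#'   \code{si_true}).
#' @export
generateTitrationSeries <- function(model, amounts, seed,
                                    n_events = 20000L,
                                    antibody = "antibody") {
    stopifnot(inherits(model, "binding_model"))
    if (!length(amounts)) abort("empty amounts", "spec_error")
    stopifnot(all(amounts > 0))
    amounts <- sort(amounts)
    pairs <- list()
    truth <- data.frame(amount = amounts, mfi_ab_true = NA_real_,
                        mfi_iso_true = NA_real_, si_true = NA_real_)
    for (k in seq_along(amounts)) {
        cc <- amounts[[k]]
        mu_ab <- model$background + model$Bmax * cc / (model$Kd + cc) +
            model$slope * cc
        mu_iso <- model$background + model$slope * cc
        spec_ab <- syntheticSampleSpec(mu_ab, model$cv, n_events,
                                       condition = "stained",
                                       antibody = antibody, amount = cc)
        spec_iso <- syntheticSampleSpec(mu_iso, model$cv, n_events,
                                        condition = "isotype",
                                        antibody = antibody, amount = cc)
        pairs[[as.character(cc)]] <-
            generateStainPair(spec_ab, spec_iso, seed + 2L * k)
        truth$mfi_ab_true[k] <- mu_ab
        truth$mfi_iso_true[k] <- mu_iso
        truth$si_true[k] <- (mu_ab - mu_iso) / (2 * mu_iso * model$cv)
    }
    list(pairs = pairs, truth = truth, antibody = antibody)
}

#' Blocking condition descriptor
#'
#' The two standard pre-incubation conditions are 300-fold molar excess
#' for 1 h at 37C and 600-fold for 2 h at RT.
#'
#' @param blocker one of \code{aSyn_monomer}, \code{aSyn_aggregate},
#'   \code{bSyn}, \code{gSyn}, \code{tubulin}, \code{mix_ab},
#'   \code{mix_abg}.
#' @param fold molar excess of blocker over antibody (default 600).
#' @param temperature \code{"RT"} or \code{"37C"}.
#' @param duration pre-incubation time in hours.
#' @return a \code{blocking_condition} list.
#' @export
blockingCondition <- function(blocker, fold = 600, temperature = "RT",
                              duration = 2) {
    stopifnot(blocker %in% c("aSyn_monomer", "aSyn_aggregate", "bSyn",
                             "gSyn", "tubulin", "mix_ab", "mix_abg"),
              fold > 0, temperature %in% c("RT", "37C"), duration > 0)
    structure(list(blocker = blocker, fold = fold,
                   temperature = temperature, duration = duration),
              class = "blocking_condition")
}

#' Ground-truth cross-reactivity for the blocking generator
#'
#' \code{kappa} maps each blocker to the fraction of the specific signal
#' it removes at the 600-fold reference excess. At other excess folds
#' the effective fraction is \code{kappa * (fold / 600)^h}; the default
#' \code{h = 0} encodes saturation (both standard conditions block
#' equally), matching the observed insensitivity to the pre-incubation
#' condition.
#'
#' @param kappa named numeric vector in [0, 1] per blocker.
#' @param h excess-fold scaling exponent (default 0).
#' @return a \code{blocking_truth} list.
#' @export
blockingTruth <- function(kappa, h = 0) {
    stopifnot(all(kappa >= 0 & kappa <= 1))
    structure(list(kappa = kappa, h = h), class = "blocking_truth")
}

#' Generate a synthetic blocking experiment
#'
#' Blocking acts multiplicatively on the specific signal component only:
#' stained mean = background + specific; blocked mean =
#' background + (1 - kappa_eff) * specific; no-stain mean = background.
#' The ground-truth efficiency under the workflow's formula is therefore
#' exactly \code{kappa_eff}.
#'
#' @param truth a \code{\link{blockingTruth}}.
#' @param condition a \code{\link{blockingCondition}}.
#' @param specific specific signal component of the stained sample.
#' @param background background (no-stain) mean.
#' @param cv arithmetic CV of each population.
#' @param n_events events per sample.
#' @param seed RNG seed.
#' @param antibody antibody label.
#' @return list: \code{stained}, \code{blocked}, \code{nostain} samples
#'   (from \code{\link{generateSample}}) and \code{truth} with
#'   \code{kappa_effective}.
#' @export
generateBlockingExperiment <- function(truth, condition, specific,
                                       background = 100, cv = 0.5,
                                       n_events = 20000L, seed = 1L,
                                       antibody = "antibody") {
    stopifnot(inherits(truth, "blocking_truth"),
              inherits(condition, "blocking_condition"))
    if (!condition$blocker %in% names(truth$kappa))
        abort(paste0("unknown blocker '", condition$blocker,
                     "' in blocking truth"), "spec_error")
    k_eff <- truth$kappa[[condition$blocker]] *
        (condition$fold / 600)^truth$h
    mk <- function(mu, cond, offset)
        generateSample(syntheticSampleSpec(mu, cv, n_events,
                                           condition = cond,
                                           antibody = antibody),
                       seed + offset)
    list(stained = mk(background + specific, "stained", 0L),
         blocked = mk(background + (1 - k_eff) * specific,
                      paste0("blocked:", condition$blocker), 1L),
         nostain = mk(background, "no-stain", 2L),
         truth = list(kappa_effective = k_eff, specific = specific,
                      background = background, condition = condition))
}

#' Measure a generated blocking experiment
#'
#' Gates the three samples through one hierarchy and applies the
#' blocking-efficiency formula to their MFIs.
#'
#' @param experiment output of \code{\link{generateBlockingExperiment}}.
#' @param hierarchy a \linkS4class{GateHierarchy}.
#' @param channel fluorescence channel.
#' @return list: \code{efficiency} (with QC flag attribute) and the
#'   three MFIs.
#' @export
measureBlocking <- function(experiment, hierarchy = defaultHierarchy(),
                            channel = "FL1") {
    mfi <- vapply(experiment[c("stained", "blocked", "nostain")],
        function(s) {
            g <- subsetEvents(s$table, applyHierarchy(s$table, hierarchy))
            populationStats(g, channel)[["MFI"]]
        }, numeric(1L))
    eff <- blockingEfficiency(mfi[["stained"]], mfi[["blocked"]],
                              mfi[["nostain"]])
    list(efficiency = eff, mfi_stained = mfi[["stained"]],
         mfi_blocked = mfi[["blocked"]], mfi_nostain = mfi[["nostain"]])
}

#' Generate a synthetic two-channel immunocytochemistry image
#'
#' The marker channel contains neurite-like ribbons and/or somatic disks
#' at a configured foreground intensity over background, plus optional
#' Gaussian noise; the target channel has configurable intensity inside
#' and outside the marker-positive region. Ground truth records the
#' geometry mask and the inside-mean.
#'
#' @param width,height image size in pixels.
#' @param shapes list of shapes: \code{list(type = "disk", cx, cy, r)}
#'   or \code{list(type = "ribbon", x0, y0, x1, y1, thickness)}.
#' @param marker_fg,marker_bg marker intensities in/outside shapes.
#' @param target_in,target_out target intensities in/outside shapes.
#' @param noise_sd Gaussian noise SD added to both channels (default 0).
#' @param seed RNG seed (needed when \code{noise_sd > 0}).
#' @return list: \code{image} (a \linkS4class{TwoChannelImage}) and
#'   \code{truth} (logical mask, \code{target_in}, \code{mask_fraction}).
#' @export
generateICCImage <- function(width = 128L, height = 128L, shapes,
                             marker_fg = 200, marker_bg = 10,
                             target_in = 50, target_out = 5,
                             noise_sd = 0, seed = 1L) {
    if (!length(shapes)) abort("no shapes given", "spec_error")
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), times = width), height, width)
    mask <- matrix(FALSE, height, width)
    for (s in shapes) {
        hit <- switch(s$type,
            disk = (xs - s$cx)^2 + (ys - s$cy)^2 <= s$r^2,
            ribbon = {
                dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
                len2 <- dx^2 + dy^2
                if (len2 == 0)
                    abort("degenerate ribbon (zero length)", "spec_error")
                t <- pmin(1, pmax(0, ((xs - s$x0) * dx + (ys - s$y0) * dy) /
                                      len2))
                (xs - (s$x0 + t * dx))^2 + (ys - (s$y0 + t * dy))^2 <=
                    (s$thickness / 2)^2
            },
            abort(paste0("unknown shape type '", s$type, "'"), "spec_error"))
        if (!any(hit))
            abort("shape lies outside the image bounds", "spec_error")
        mask <- mask | hit
    }
    withSeed(seed, {
        marker <- ifelse(mask, marker_fg, marker_bg)
        target <- ifelse(mask, target_in, target_out)
        if (noise_sd > 0) {
            marker <- marker + rnorm(length(marker), 0, noise_sd)
            target <- target + rnorm(length(target), 0, noise_sd)
        }
        marker <- pmax(matrix(marker, height, width), 0)
        target <- pmax(matrix(target, height, width), 0)
        list(image = TwoChannelImage(marker, target),
             truth = list(mask = mask, target_in = target_in,
                          mask_fraction = mean(mask)))
    })
}
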