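#' Standard two-sided group comparisons
#'
#' Thin delegation to the classical tests used for condition comparisons:
#' equal-variance two-sample t-test, Mann-Whitney U, Kolmogorov-Smirnov, or
#' one-way ANOVA with Tukey's post hoc. For the pairwise tests all group
#' pairs are compared and the p-values adjusted by the requested correction;
#' Tukey's HSD carries its own multiplicity adjustment.
#'
#' @param groups Named list of >= 2 numeric vectors, each of length >= 3.
#' @param test One of `"t"`, `"mann_whitney"`, `"ks"`, `"anova_tukey"`.
#' @param correction `"none"`, `"bonferroni"` or `"holm_sidak"` (ignored for
#'   `"anova_tukey"`).
#' @return data.frame with `group1`, `group2`, `p`, `p_adj`.
#' @export
#' @examples
#' group_compare(list(a = rnorm(10), b = rnorm(10, 2)), test = "t")
group_compare <- function(groups,
                          test = c("t", "mann_whitney", "ks", "anova_tukey"),
                          correction = c("none", "bonferroni", "holm_sidak")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (length(groups) < 2) stop_param("at least 2 groups are required")
  if (any(vapply(groups, length, numeric(1)) < 3))
    stop_param("each group needs n >= 3")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))

  if (test == "anova_tukey") {
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(names(groups),
                                    vapply(groups, length, numeric(1)))))
    tk <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    return(data.frame(group1 = vapply(pairs, `[`, "", 2),
                      group2 = vapply(pairs, `[`, "", 1),
                      p = tk[, "p adj"], p_adj = tk[, "p adj"],
                      row.names = NULL))
  }

  combs <- utils::combn(names(groups), 2)
  p <- apply(combs, 2, function(nm) {
    a <- groups[[nm[1]]]; b <- groups[[nm[2]]]
    if (test == "t") {
      if (stats::sd(c(a, b)) == 0)
        stop_param("degenerate variance: t-test undefined for constant groups")
      stats::t.test(a, b, var.equal = TRUE)$p.value
    } else if (test == "mann_whitney") {
      if (length(unique(c(a, b))) == 1) 1
      else suppressWarnings(stats::wilcox.test(a, b)$p.value)
    } else {
      if (length(unique(c(a, b))) == 1) 1
      else suppressWarnings(stats::ks.test(a, b)$p.value)
    }
  })
  m <- length(p)
  p_adj <- switch(correction,
    none = p,
    bonferroni = pmin(p * m, 1),
    holm_sidak = {
      o <- order(p)
      adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
      adj <- cummax(adj)
      out <- numeric(m); out[o] <- pmin(adj, 1); out
    })
  data.frame(group1 = combs[1, ], group2 = combs[2, ], p = p, p_adj = p_adj)
}

stage_handlers <- function() list(
  bleach = function(params, seed) {
    p <- utils::modifyList(list(x = 0.12, p = 0.8, n_motors = 108), params)
    h <- sim_bleach_counts(p$x, p$p, p$n_motors, seed)
    fit <- fit_oligomer(h)
    list(histogram = as.list(h$counts), x_hat = fit$x_hat, p_hat = fit$p_hat,
         truth = list(x = p$x, p = p$p))
  },
  hydro = function(params, seed) {
    p <- utils::modifyList(list(rs_nm = 4.9, s_svedberg = 7.4,
                                noise_sd = 0), params)
    sec <- sim_elution(-0.014, 0.97, "log10_anchor", sec_standards,
                       p$rs_nm, volumes = seq(0, 40, by = 0.5),
                       noise_sd = p$noise_sd, seed = seed)
    grad <- sim_elution(5.66, -3.92, "identity_anchor", gradient_standards,
                        p$s_svedberg, volumes = seq(0.2, 4.2, by = 0.2),
                        noise_sd = p$noise_sd, seed = seed + 1)
    std_from <- function(sim, anchors) data.frame(
      anchor_value = anchors,
      elution_volume_ml = vapply(names(anchors), function(nm)
        locate_peak(sim$profiles[[nm]])$centre, numeric(1)))
    res <- hydrodynamic_result(std_from(sec, sec_standards),
                               std_from(grad, gradient_standards),
                               sec$profiles$sample, grad$profiles$sample)
    list(rs_nm = res$rs_nm, s_svedberg = res$s_svedberg,
         mw_da = res$mw_da, f_ratio = res$f_ratio)
  },
  motility = function(params, seed) {
    p <- utils::modifyList(list(n_mt = 10, mt_length = 15, duration = 3),
                           params)
    truth <- do.call(motility_truth,
                     params[intersect(names(params),
                                      names(formals(motility_truth)))])
    obs <- lapply(seq_len(p$n_mt), function(i)
      sim_motility(p$mt_length, p$duration, truth, seed = seed + i))
    ev <- do.call(rbind, lapply(obs, `[[`, "events"))
    s <- summarize_motility(ev, obs)
    list(n_events = s$n_events, mean_speed = s$mean_speed,
         mean_run_length = s$mean_run_length,
         run_length_mle = s$run_length_mle,
         landing_rate = s$landing_rate)
  },
  binding = function(params, seed) {
    p <- utils::modifyList(list(kd = 1, noise_cv = 0.02), params)
    ser <- sim_binding_series(p$kd, noise_cv = p$noise_cv, seed = seed)
    fit <- fit_kd(ser)
    list(kd = fit$kd, f_free = fit$f_free, f_bound = fit$f_bound,
         truth = list(kd = p$kd))
  },
  cells = function(params, seed) {
    p <- utils::modifyList(list(tail_I = c(100, 80), cyto_I = c(20, 20),
                                bg_I = c(10, 10), noise_sd = 2), params)
    img <- sim_cell_image(p$tail_I, p$cyto_I, p$bg_I,
                          noise_sd = p$noise_sd, seed = seed)
    er <- enrichment_ratio(img, default_region_masks())
    list(ratio_ch1 = er$ratio[1], ratio_ch2 = er$ratio[2],
         channel_ratio = er$channel_ratio)
  },
  podosomes = function(params, seed) {
    p <- utils::modifyList(list(n_objects = 10, coloc_fraction = 0.8,
                                noise_sd = 5), params)
    img <- sim_podosome_image(p$n_objects, coloc_fraction = p$coloc_fraction,
                              noise_sd = p$noise_sd, seed = seed)
    det <- count_podosomes(img)
    list(count = det$count,
         truth = list(n_coincident = attr(img, "truth")$n_coincident))
  })

#' Run a configuration-driven analysis pipeline
#'
#' Executes the requested closed-loop stages (simulate with known ground
#' truth, then analyse) in order and assembles a report bundle. Identical
#' config and seed yield an identical bundle; serialising it with
#' [write_report()] gives byte-identical JSON.
#'
#' @param config A list (or path to a YAML/JSON file) with fields `seed`
#'   (integer) and `stages`: a list of entries, each with `stage` (one of
#'   `"bleach"`, `"hydro"`, `"motility"`, `"binding"`, `"cells"`,
#'   `"podosomes"`) and optional `params`.
#' @return A `report_bundle`: `results` (one entry per stage), `provenance`
#'   (config hash, seed, package version) and `errors` (per-stage failure
#'   records, if any).
#' @export
#' @examples
#' b <- run_pipeline(list(seed = 1, stages = list(list(stage = "bleach"))))
#' b$results$bleach$x_hat
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
    else yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$seed) || is.null(config$stages))
    stop_param("config error: fields `seed` and `stages` are required")
  seed <- config$seed
  if (!is.numeric(seed) || seed != floor(seed) || seed < 0)
    stop_param("config error at `seed`: must be a non-negative integer")
  handlers <- stage_handlers()
  results <- list(); errors <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(handlers))
      stop_param("config error at `stages[[%d]]$stage`: must be one of %s",
                 i, paste(names(handlers), collapse = ", "))
    params <- if (is.null(st$params)) list() else st$params
    out <- tryCatch(handlers[[st$stage]](params, seed + 1000L * i),
                    error = function(e) e)
    if (inherits(out, "error")) {
      errors[[st$stage]] <- conditionMessage(out)
    } else {
      results[[st$stage]] <- out
    }
  }
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(config, cfg_file, version = 3, compress = FALSE)
  hash <- unname(tools::md5sum(cfg_file))
  structure(list(results = results,
                 provenance = list(config_hash = hash, seed = seed,
                                   package_version =
                                     as.character(utils::packageVersion("motorquant"))),
                 errors = errors),
            class = "report_bundle")
}

#' Serialise a report bundle to JSON
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(bundle, path = NULL) {
  js <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle (seed ", x$provenance$seed, "): stages ",
      paste(names(x$results), collapse = ", "), "\n", sep = "")
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
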