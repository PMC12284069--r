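#' Normality-gated statistical test selection
#'
#' Implements the study's test-selection rule: every group is tested for
#' normality with Shapiro-Wilk; parametric tests are used only when ALL
#' groups pass at `alpha_normality`. Routing:
#'
#' | design | all normal | any non-normal |
#' |---|---|---|
#' | two groups, unpaired | two-tailed Student's t (pooled variance) | Mann-Whitney U |
#' | two groups, paired | two-tailed paired t | Wilcoxon signed-rank |
#' | > 2 groups, unpaired | one-way ANOVA | Kruskal-Wallis |
#' | > 2 groups, paired/RM | one-way repeated-measures ANOVA | Kruskal-Wallis |
#'
#' @param groups named list of numeric vectors, >= 2 groups with n >= 3 each
#'   (the Shapiro-Wilk minimum); paired designs need equal lengths, with
#'   element k of each group from the same subject.
#' @param paired logical.
#' @param alpha_normality Shapiro-Wilk level (default 0.05).
#' @return list `test` (name), `statistic`, `df`, `p.value`, `parametric`,
#'   `shapiro_p` (per group).
#' @export
select_and_run_test <- function(groups, paired = FALSE, alpha_normality = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 3L)) stop("every group needs n >= 3 for the Shapiro-Wilk gate")
  if (paired && length(unique(ns)) != 1L)
    stop("paired design requires equal group sizes")
  sw <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  normal <- all(sw >= alpha_normality)
  k <- length(groups)
  if (k == 2L) {
    if (normal) {
      if (paired && stats::sd(groups[[1L]] - groups[[2L]]) == 0) {
        # degenerate pairs: constant difference has zero variance, so the t
        # statistic is 0/0 (identical groups) or +/-Inf (constant offset)
        d1 <- mean(groups[[1L]] - groups[[2L]])
        res <- list(test = "paired t-test",
                    statistic = if (d1 == 0) 0 else sign(d1) * Inf,
                    df = ns[1L] - 1, p.value = if (d1 == 0) 1 else 0)
      } else {
        tt <- stats::t.test(groups[[1L]], groups[[2L]], paired = paired,
                            var.equal = !paired)
        res <- list(test = if (paired) "paired t-test" else "unpaired t-test",
                    statistic = unname(tt$statistic), df = unname(tt$parameter),
                    p.value = tt$p.value)
      }
    } else if (paired) {
      w <- signed_rank_test(groups[[1L]], groups[[2L]])
      res <- list(test = "Wilcoxon signed-rank", statistic = w$statistic,
                  df = NA_real_, p.value = w$p.value)
    } else {
      w <- stats::wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE,
                              correct = TRUE)
      res <- list(test = "Mann-Whitney U", statistic = unname(w$statistic),
                  df = NA_real_, p.value = w$p.value)
    }
  } else {
    values <- unlist(groups, use.names = FALSE)
    cond <- factor(rep(names(groups) %||% seq_along(groups), ns))
    if (normal && paired) {
      subj <- factor(unlist(lapply(ns, seq_len)))
      a <- rm_anova_oneway(values, cond, subj)
      res <- list(test = "one-way RM ANOVA", statistic = a$F,
                  df = c(a$df1, a$df2), p.value = a$p.value)
    } else if (normal) {
      a <- summary(stats::aov(values ~ cond))[[1L]]
      res <- list(test = "one-way ANOVA", statistic = a[1L, "F value"],
                  df = c(a[1L, "Df"], a[2L, "Df"]), p.value = a[1L, "Pr(>F)"])
    } else {
      kw <- stats::kruskal.test(values, cond)
      res <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p.value = kw$p.value)
    }
  }
  c(res, list(parametric = normal, shapiro_p = sw))
}

#' Group comparison of head-fixed coping metrics
#'
#' The default spontaneous-AC pipeline applied to two cohorts of motion
#' traces: each trace is low-pass filtered and segmented
#' ([detect_bouts_filtered()]), summarized into total AC time and AC bout
#' count, and the two per-animal metrics are compared across groups with the
#' normality-gated test selection ([select_and_run_test()]).
#'
#' @param traces_a,traces_b lists of [time_trace()] motion-index traces, one
#'   per animal, for the two groups (e.g. control vs astrocyte-IP3R
#'   knockout).
#' @param params a [detection_params()]; default spontaneous.
#' @return list `per_animal` (data.frame `group`, `animal`, `total_ac_s`,
#'   `n_ac_bouts`), `total_ac_test`, `n_bouts_test`.
#' @export
headfixed_group_comparison <- function(traces_a, traces_b,
                                       params = detection_params("spontaneous")) {
  summar <- function(traces, grp) {
    do.call(rbind, lapply(seq_along(traces), function(i) {
      s <- summarize_bouts(detect_bouts_filtered(traces[[i]], params))
      data.frame(group = grp, animal = i, total_ac_s = s$total_active_s,
                 n_ac_bouts = s$n_active_bouts)
    }))
  }
  pa <- rbind(summar(traces_a, "A"), summar(traces_b, "B"))
  list(per_animal = pa,
       total_ac_test = select_and_run_test(
         split(pa$total_ac_s, pa$group), paired = FALSE),
       n_bouts_test = select_and_run_test(
         split(as.numeric(pa$n_ac_bouts), pa$group), paired = FALSE))
}

#' DREADD sign-inversion repeated-measures ANOVA
#'
#' For alternating saline/CNO sessions, astrocyte activation is expected to
#' move total AC time (or bout count) in opposite directions across the two
#' transition types. Per animal and per consecutive session pair, the change
#' `session[k+1] - session[k]` is computed; changes across Saline -> CNO
#' transitions are multiplied by -1 so both transition types share the
#' expected sign; the inverted deltas are then compared across transition
#' types by one-way repeated-measures ANOVA with animal as the repeated
#' factor (multiple transitions of one type within an animal are averaged
#' first).
#'
#' @param sessions data.frame with columns `animal`, `order` (session index
#'   within animal), `label` (`"Saline"`/`"CNO"`), `value` (total AC seconds
#'   or bout count). Labels must strictly alternate within every animal.
#' @return list `deltas` (data.frame `animal`, `transition`, `delta` after
#'   inversion), `anova` ([rm_anova_oneway()] result).
#' @export
dreadd_inversion_rm_anova <- function(sessions) {
  need <- c("animal", "order", "label", "value")
  if (!all(need %in% names(sessions))) stop("sessions needs columns ", paste(need, collapse = ", "))
  out <- NULL
  for (a in unique(sessions$animal)) {
    s <- sessions[sessions$animal == a, ]
    s <- s[order(s$order), ]
    if (nrow(s) < 2L) stop("animal ", a, " has fewer than 2 sessions")
    if (any(s$label[-1L] == s$label[-nrow(s)]))
      stop("non-alternating session labels for animal ", a)
    delta <- diff(s$value)
    from <- s$label[-nrow(s)]
    to <- s$label[-1L]
    delta[from == "Saline" & to == "CNO"] <- -delta[from == "Saline" & to == "CNO"]
    out <- rbind(out, data.frame(animal = a,
                                 transition = paste(from, to, sep = "->"),
                                 delta = delta))
  }
  agg <- stats::aggregate(delta ~ animal + transition, data = out, FUN = mean)
  nlev <- length(unique(agg$transition))
  if (stats::var(agg$delta) == 0) {
    # degenerate: identical deltas everywhere carry no transition-type signal
    res <- list(F = 0, df1 = nlev - 1L,
                df2 = (nlev - 1L) * (length(unique(agg$animal)) - 1L),
                p.value = 1)
  } else {
    res <- rm_anova_oneway(agg$delta, agg$transition, agg$animal)
  }
  list(deltas = out, anova = res)
}

#' Build a rabies cell-count table
#'
#' @param region,animal character vectors.
#' @param section integer section index (consecutive within animal/region;
#'   adjacent sections differ by 1).
#' @param rv_positive rabies-positive cell count, >= 0.
#' @param neun_positive_rv count of rabies-positive cells that are also
#'   NeuN-positive; rowwise `<= rv_positive`.
#' @return a `CountTable` data.frame.
#' @export
count_table <- function(region, animal, section, rv_positive,
                        neun_positive_rv = NA_integer_) {
  df <- data.frame(region = as.character(region), animal = as.character(animal),
                   section = as.integer(section),
                   rv_positive = as.integer(rv_positive),
                   neun_positive_rv = as.integer(neun_positive_rv))
  if (any(df$rv_positive < 0, na.rm = TRUE)) stop("counts must be >= 0")
  bad <- !is.na(df$neun_positive_rv) & df$neun_positive_rv > df$rv_positive
  if (any(bad)) stop("neun_positive_rv must not exceed rv_positive")
  structure(df, class = c("CountTable", "data.frame"))
}

#' Region-inclusion filter for rabies tracing
#'
#' A brain region is included when more than 3 animals (i.e. at least 4)
#' each show more than 5 rabies-positive cells on 2 adjacent sections. The
#' canonical reading sums the counts over an adjacent section pair and
#' requires the sum to exceed 5 (`per_section = FALSE`); the stricter
#' alternative requires each section of some adjacent pair to individually
#' exceed 5 (`per_section = TRUE`). All inequalities are strict.
#'
#' @param table a [count_table()].
#' @param min_cells cells threshold (strict >, default 5).
#' @param min_animals animals threshold expressed as "more than"
#'   (strict >, default 3, i.e. >= 4 animals).
#' @param per_section see above; default `FALSE` (sum over the pair).
#' @return character vector of included regions.
#' @export
rabies_region_filter <- function(table, min_cells = 5, min_animals = 3,
                                 per_section = FALSE) {
  if (nrow(table) == 0L) return(character(0))
  qualifies <- function(counts, sections) {
    o <- order(sections)
    s <- sections[o]; x <- counts[o]
    adj <- which(diff(s) == 1L)
    if (!length(adj)) return(FALSE)
    if (per_section) any(x[adj] > min_cells & x[adj + 1L] > min_cells)
    else any(x[adj] + x[adj + 1L] > min_cells)
  }
  included <- character(0)
  for (rg in unique(table$region)) {
    tr <- table[table$region == rg, ]
    n_ok <- sum(vapply(unique(tr$animal), function(a) {
      ta <- tr[tr$animal == a, ]
      qualifies(ta$rv_positive, ta$section)
    }, logical(1)))
    if (n_ok > min_animals) included <- c(included, rg)
  }
  included
}

#' Animal-level exclusion for rabies tracing
#'
#' An animal is excluded when the starter-virus expression spread outside
#' the LHb exceeds 30% or the fraction of starter cells that are neuronal
#' exceeds 0.5% (both strict inequalities). Animals with missing metadata
#' are flagged rather than silently included.
#'
#' @param meta data.frame with columns `animal`, `starter_spread_outside_frac`,
#'   `starter_neuronal_frac` (fractions in `[0, 1]`).
#' @param max_spread,max_neuronal exclusion thresholds (defaults 0.30 and
#'   0.005).
#' @return data.frame `animal`, `include` (logical; `NA` when flagged),
#'   `reason`.
#' @export
rabies_animal_exclusion <- function(meta, max_spread = 0.30, max_neuronal = 0.005) {
  res <- data.frame(animal = meta$animal, include = NA, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    sp <- meta$starter_spread_outside_frac[i]
    ne <- meta$starter_neuronal_frac[i]
    if (is.na(sp) || is.na(ne)) {
      res$include[i] <- NA
      res$reason[i] <- "missing starter metadata; flagged for manual review"
    } else if (sp > max_spread) {
      res$include[i] <- FALSE
      res$reason[i] <- sprintf("spread outside LHb %.3g > %.3g", sp, max_spread)
    } else if (ne > max_neuronal) {
      res$include[i] <- FALSE
      res$reason[i] <- sprintf("neuronal starter fraction %.3g > %.3g", ne, max_neuronal)
    } else {
      res$include[i] <- TRUE
      res$reason[i] <- "passed both starter criteria"
    }
  }
  res
}

#' Neuronal fraction of rabies-positive cells per region
#'
#' Pooled fraction RV+NeuN+ / RV+ per region across the included animals
#' (rows from excluded animals are ignored). Regions with a zero pooled RV+
#' total get `NA`.
#'
#' @param table a [count_table()] with `neun_positive_rv` filled.
#' @param regions regions to summarize (default: all in the table).
#' @param included_animals animals to pool over (default: all).
#' @return data.frame `region`, `rv_total`, `neun_total`, `neuronal_frac`.
#' @export
neuronal_fraction_summary <- function(table, regions = unique(table$region),
                                      included_animals = unique(table$animal)) {
  out <- data.frame(region = regions, rv_total = NA_integer_,
                    neun_total = NA_integer_, neuronal_frac = NA_real_)
  for (i in seq_along(regions)) {
    tr <- table[table$region == regions[i] & table$animal %in% included_animals, ]
    rv <- sum(tr$rv_positive, na.rm = TRUE)
    ne <- sum(tr$neun_positive_rv, na.rm = TRUE)
    out$rv_total[i] <- rv
    out$neun_total[i] <- ne
    out$neuronal_frac[i] <- if (rv > 0) ne / rv else NA_real_
  }
  out
}
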