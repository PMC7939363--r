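# floor(x / bin) robust to floating-point representation of bin edges
bin_floor <- function(x, bin) floor(round(x / bin, 9))

#' Genotype-phenotype map regression per parameter
#'
#' Builds, for each mutated parameter, the regression of "genetic" distance
#' against morphological distance over the parent's IS one-mutant
#' neighborhood.  The members of a parameter's series are the 8 mutants
#' (-80% to +80%) plus the unmutated parent at 0% perturbation.  The
#' genetic distance between two members is the absolute difference of
#' their perturbation percentages (0 to 160%).  For the EMD and CMD
#' metrics, the morphological distance of a member pair is the mean
#' distance between all twins of one member and all twins of the other,
#' and each member additionally contributes its own twin-pair distances at
#' the 0% position (its developmental instability).  For HMD the distance
#' is between the two members' mean morphologies and there is no 0%
#' position.  The regression coefficient `beta` is the ordinary
#' least-squares slope; a large `beta` means small genetic changes produce
#' large morphological changes (a complex GPM).
#'
#' @param parent_twins List of parent twin morphologies (the 0% member).
#' @param records A `mutation_records` tibble from [is_neighborhood()].
#' @param metric `"emd"`, `"cmd"` or `"hmd"`.
#' @return Tibble of class `gpm_regression`: one row per parameter with
#'   `param`, `metric`, `beta`, `intercept`, `n_points`, `n_dropped`
#'   (aberrant-only members), and the regression points as a list-column.
#' @export
gpm_regression <- function(parent_twins, records,
                           metric = c("emd", "cmd", "hmd")) {
  metric <- match.arg(metric)
  records <- records[records$kind == "IS", ]
  out <- list()
  for (p in unique(records$param)) {
    rec <- records[records$param == p, ]
    members <- c(list(list(mag = 0, twins = parent_twins)),
                 lapply(seq_len(nrow(rec)), function(i) {
                   list(mag = rec$magnitude[i], twins = rec$twins[[i]])
                 }))
    ok <- vapply(members, function(m) length(m$twins) >= 1, logical(1))
    n_dropped <- sum(!ok)
    members <- members[ok]
    xs <- c(); ys <- c()
    if (metric == "hmd") {
      means <- lapply(members, function(m) mean_morphology(m$twins))
      for (i in seq_along(members)) {
        for (j in seq_along(members)) {
          if (j <= i) next
          xs <- c(xs, abs(members[[i]]$mag - members[[j]]$mag))
          ys <- c(ys, hmd(means[[i]], means[[j]]))
        }
      }
    } else {
      for (i in seq_along(members)) {
        if (length(members[[i]]$twins) >= 2) {
          xs <- c(xs, 0)
          ys <- c(ys, pairwise_distance(members[[i]]$twins, metric))
        }
        for (j in seq_along(members)) {
          if (j <= i) next
          xs <- c(xs, abs(members[[i]]$mag - members[[j]]$mag))
          ys <- c(ys, cross_distance(members[[i]]$twins,
                                     members[[j]]$twins, metric))
        }
      }
    }
    fit <- lm(ys ~ xs)
    out[[length(out) + 1L]] <- tibble::tibble(
      param = p, metric = metric,
      beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      n_points = length(xs), n_dropped = n_dropped,
      points = list(tibble::tibble(genetic = xs, morphological = ys)))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("gpm_regression", class(res))
  res
}

#' @export
tidy.gpm_regression <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"points")
}

#' @export
glance.gpm_regression <- function(x, ...) {
  tibble::tibble(n_params = nrow(x), metric = x$metric[1],
                 mean_beta = mean(x$beta), median_beta = stats::median(x$beta),
                 max_beta = max(x$beta))
}

#' Mutational asymmetry histogram
#'
#' Two-dimensional histogram of offspring complexity change against parent
#' complexity: offspring are binned along x by their parent's complexity
#' and along y by their own complexity minus the parental complexity.
#' Within each x column the counts are normalized to relative abundances
#' summing to one, and the natural logarithm of the relative abundance is
#' reported.  Empty cells are absent from the output (not `-Inf`).  Default
#' bin sizes: 0.03 AV units, 1 OPC unit.
#'
#' @param parent_scores Numeric vector: complexity of each offspring's
#'   parent.
#' @param offspring_scores Numeric vector: complexity of each offspring.
#' @param measure `"av"` or `"opc"` (selects the default bin size).
#' @param bin Bin size override.
#' @return Tibble with `parent_bin`, `delta_bin` (bin lower edges),
#'   `count`, `rel_abundance`, `log_rel_abundance`.
#' @export
asymmetry_histogram <- function(parent_scores, offspring_scores,
                                measure = c("av", "opc"), bin = NULL) {
  measure <- match.arg(measure)
  stopifnot(length(parent_scores) == length(offspring_scores))
  if (is.null(bin)) bin <- if (measure == "av") 0.03 else 1
  ok <- is.finite(parent_scores) & is.finite(offspring_scores)
  px <- parent_scores[ok]
  dy <- offspring_scores[ok] - parent_scores[ok]
  tb <- tibble::tibble(
    parent_bin = bin_floor(px, bin) * bin,
    delta_bin = bin_floor(dy, bin) * bin)
  tb <- dplyr::count(tb, .data$parent_bin, .data$delta_bin, name = "count")
  tb <- dplyr::mutate(
    dplyr::group_by(tb, .data$parent_bin),
    rel_abundance = .data$count / sum(.data$count))
  tb <- dplyr::ungroup(tb)
  dplyr::mutate(tb, log_rel_abundance = log(.data$rel_abundance))
}

#' Complexity frequency spectrum of an ensemble
#'
#' Histogram of complexity scores over the ensemble: the frequency of
#' morphologies in each complexity bin.
#'
#' @param scores Numeric vector of complexity scores.
#' @param measure `"av"` or `"opc"`.
#' @param bin Bin size (defaults: 0.03 AV, 1 OPC).
#' @return Tibble with `bin` (lower edge), `mid`, `count`, `frequency`.
#' @export
frequency_spectrum <- function(scores, measure = c("av", "opc"),
                               bin = NULL) {
  measure <- match.arg(measure)
  stopifnot(length(scores) >= 1)
  if (is.null(bin)) bin <- if (measure == "av") 0.03 else 1
  tb <- dplyr::count(
    tibble::tibble(bin = bin_floor(scores, bin) * bin), .data$bin,
    name = "count")
  dplyr::mutate(tb, mid = .data$bin + bin / 2,
                frequency = .data$count / sum(.data$count))
}

#' Degeneracy heatmap across complexity intervals
#'
#' Measures how morphologically similar the morphologies of different
#' mechanisms are, per complexity interval: samples up to `n_per`
#' mechanisms per interval and computes the mean homologous morphological
#' distance (HMD) between all sampled pairs for every interval pair.
#' Diagonal entries come from within-interval pairs.  Default interval
#' grids: 0 to 1.2 in 0.1 AV steps, 0 to 25 in 2 OPC steps.  Intervals
#' without members are marked missing (`NA`), not zero.
#'
#' @param ensemble Ensemble tibble from [generate_ensemble()] (uses the
#'   `morphology` list-column and the chosen score column).
#' @param measure `"av"` or `"opc"`.
#' @param breaks Interval boundaries.
#' @param n_per Mechanisms sampled per interval (default 20).
#' @param seed Sampling seed.
#' @return List with `matrix` (symmetric mean-HMD matrix, intervals in
#'   rows/columns) and `counts` (members sampled per interval).
#' @export
degeneracy_heatmap <- function(ensemble, measure = c("av", "opc"),
                               breaks = NULL, n_per = 20, seed = 1) {
  measure <- match.arg(measure)
  if (is.null(breaks)) {
    breaks <- if (measure == "av") seq(0, 1.2, 0.1) else seq(0, 25, 2)
  }
  scores <- ensemble[[measure]]
  k <- length(breaks) - 1
  idx <- with_seed(seed, lapply(seq_len(k), function(b) {
    hit <- which(scores >= breaks[b] & scores < breaks[b + 1])
    if (length(hit) > n_per) sample(hit, n_per) else hit
  }))
  M <- matrix(NA_real_, k, k)
  lab <- sprintf("[%.2g,%.2g)", breaks[-(k + 1)], breaks[-1])
  dimnames(M) <- list(lab, lab)
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- idx[[a]]; ib <- idx[[b]]
      if (!length(ia) || !length(ib)) next
      vals <- c()
      for (i in ia) {
        for (j in ib) {
          if (a == b && j <= i) next
          vals <- c(vals, hmd(ensemble$morphology[[i]],
                              ensemble$morphology[[j]]))
        }
      }
      if (length(vals)) M[a, b] <- M[b, a] <- mean(vals)
    }
  }
  list(matrix = M, counts = vapply(idx, length, integer(1)),
       breaks = breaks)
}
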