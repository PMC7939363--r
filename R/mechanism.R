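#' Construct a developmental mechanism
#'
#' A developmental mechanism is a gene network plus the cell behaviors and
#' mechanical properties it regulates.  The network is a signed weighted
#' interaction matrix `T` where `T[l, k]` is the strength with which gene
#' product `l` activates (positive) or inhibits (negative) gene product `k`.
#' Each gene is either intracellular or extracellularly diffusible, with
#' per-gene diffusion and degradation rates.  Couplings attach genes to
#' behaviors or mechanical properties; together with the non-zero network
#' entries and the per-gene rates they form the mechanism's mutable
#' parameter list (its "genotype").
#'
#' @param T_mat Square numeric matrix of regulatory strengths (regulator in
#'   rows, target in columns).
#' @param gene_specs Tibble with columns `gene`, `diffusible` (logical),
#'   `diffusion_rate`, `degradation_rate`.  Non-diffusible genes must have
#'   zero diffusion rate.
#' @param couplings Tibble with columns `gene`, `target` (one of
#'   `r paste0('\x60', COUPLING_TARGETS, '\x60', collapse = ", ")`), and
#'   `strength`.
#' @param default_division_rate Small default division rate shared by all
#'   cells (phase accumulated per unit time).
#' @param gradient_gene Index of the maintained-gradient input gene.
#' @return An object of class `dev_mechanism`.
#' @export
dev_mechanism <- function(T_mat,
                          gene_specs = NULL,
                          couplings = NULL,
                          default_division_rate = 0.001,
                          gradient_gene = 1L) {
  T_mat <- as.matrix(T_mat)
  stopifnot(nrow(T_mat) == ncol(T_mat), nrow(T_mat) >= 2)
  n <- nrow(T_mat)
  if (is.null(gene_specs)) {
    gene_specs <- tibble::tibble(
      gene = seq_len(n), diffusible = FALSE,
      diffusion_rate = 0, degradation_rate = 0.2)
  }
  gene_specs <- tibble::as_tibble(gene_specs)
  stopifnot(nrow(gene_specs) == n)
  if (any(!gene_specs$diffusible & gene_specs$diffusion_rate != 0)) {
    abort("non-diffusible genes must have diffusion_rate = 0")
  }
  if (is.null(couplings)) {
    couplings <- tibble::tibble(gene = integer(), target = character(),
                                strength = numeric())
  }
  couplings <- tibble::as_tibble(couplings)
  if (nrow(couplings) && !all(couplings$target %in% COUPLING_TARGETS)) {
    abort("unknown coupling target")
  }
  structure(
    list(n_genes = n, T = T_mat, gene_specs = gene_specs,
         couplings = couplings,
         default_division_rate = default_division_rate,
         gradient_gene = as.integer(gradient_gene)),
    class = "dev_mechanism")
}

#' @export
print.dev_mechanism <- function(x, ...) {
  cat(sprintf(
    "<dev_mechanism> %d genes, %d network interactions, %d behavior couplings (N_c = %d), %d parameters\n",
    x$n_genes, sum(x$T != 0), nrow(x$couplings), n_interactions(x),
    nrow(mech_parameters(x))))
  invisible(x)
}

#' Number of interactions (network entries plus behavior couplings)
#'
#' @param mech A `dev_mechanism`.
#' @return Integer count `N_c`.
#' @export
n_interactions <- function(mech) {
  as.integer(sum(mech$T != 0) + nrow(mech$couplings))
}

#' Enumerate the mutable parameters of a mechanism
#'
#' The ordered "genotype": all non-zero network interaction strengths, all
#' behavior-coupling strengths, and the non-zero per-gene diffusion and
#' degradation rates.
#'
#' @param mech A `dev_mechanism`.
#' @return Tibble with columns `param` (index), `type` (`"network"`,
#'   `"coupling"`, `"diffusion"`, `"degradation"`), `gene_from`, `gene_to`,
#'   `target`, `value`.
#' @export
mech_parameters <- function(mech) {
  nz <- which(mech$T != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  net <- tibble::tibble(
    type = rep("network", nrow(nz)),
    gene_from = as.integer(nz[, 1]), gene_to = as.integer(nz[, 2]),
    target = NA_character_, value = mech$T[nz])
  cpl <- tibble::tibble(
    type = rep("coupling", nrow(mech$couplings)),
    gene_from = as.integer(mech$couplings$gene), gene_to = NA_integer_,
    target = mech$couplings$target, value = mech$couplings$strength)
  gs <- mech$gene_specs
  dif <- tibble::tibble(
    type = "diffusion", gene_from = as.integer(gs$gene),
    gene_to = NA_integer_, target = NA_character_,
    value = gs$diffusion_rate)[gs$diffusion_rate != 0, ]
  deg <- tibble::tibble(
    type = "degradation", gene_from = as.integer(gs$gene),
    gene_to = NA_integer_, target = NA_character_,
    value = gs$degradation_rate)[gs$degradation_rate != 0, ]
  out <- dplyr::bind_rows(net, cpl, dif, deg)
  dplyr::bind_cols(tibble::tibble(param = seq_len(nrow(out))), out)
}

#' Set one mutable parameter to a new value
#'
#' @param mech A `dev_mechanism`.
#' @param param Parameter index as enumerated by [mech_parameters()].
#' @param value New value.  Degradation and diffusion rates are clamped at
#'   zero from below (negative rates are not physical).
#' @return The modified mechanism.
#' @export
set_parameter <- function(mech, param, value) {
  tab <- mech_parameters(mech)
  stopifnot(param >= 1, param <= nrow(tab))
  row <- tab[param, ]
  if (row$type == "network") {
    mech$T[row$gene_from, row$gene_to] <- value
  } else if (row$type == "coupling") {
    idx <- which(mech$couplings$gene == row$gene_from &
                   mech$couplings$target == row$target)[1]
    mech$couplings$strength[idx] <- value
  } else if (row$type == "diffusion") {
    mech$gene_specs$diffusion_rate[row$gene_from] <- max(0, value)
  } else {
    mech$gene_specs$degradation_rate[row$gene_from] <- max(0, value)
  }
  mech
}

# read / write a parameter identified by a row of mech_parameters(),
# robust to other parameters having been clamped to zero meanwhile
get_parameter_row <- function(mech, row) {
  switch(row$type,
         network = mech$T[row$gene_from, row$gene_to],
         coupling = mech$couplings$strength[
           mech$couplings$gene == row$gene_from &
             mech$couplings$target == row$target][1],
         diffusion = mech$gene_specs$diffusion_rate[row$gene_from],
         degradation = mech$gene_specs$degradation_rate[row$gene_from])
}

set_parameter_row <- function(mech, row, value) {
  if (row$type == "network") {
    mech$T[row$gene_from, row$gene_to] <- value
  } else if (row$type == "coupling") {
    idx <- which(mech$couplings$gene == row$gene_from &
                   mech$couplings$target == row$target)[1]
    mech$couplings$strength[idx] <- value
  } else if (row$type == "diffusion") {
    mech$gene_specs$diffusion_rate[row$gene_from] <- max(0, value)
  } else {
    mech$gene_specs$degradation_rate[row$gene_from] <- max(0, value)
  }
  mech
}

#' Enumerate interactions (targets of topology mutations)
#'
#' @param mech A `dev_mechanism`.
#' @return Tibble with columns `interaction`, `type` (`"network"` or
#'   `"coupling"`), `gene_from`, `gene_to`, `target`, `value`.
#' @export
mech_interactions <- function(mech) {
  tab <- mech_parameters(mech)
  tab <- tab[tab$type %in% c("network", "coupling"), ]
  dplyr::bind_cols(tibble::tibble(interaction = seq_len(nrow(tab))),
                   tab[, setdiff(names(tab), "param")])
}

#' Delete one interaction (a topology mutation)
#'
#' @param mech A `dev_mechanism`.
#' @param interaction Index as enumerated by [mech_interactions()].
#' @return The mechanism with that network entry or coupling removed.
#' @export
delete_interaction <- function(mech, interaction) {
  tab <- mech_interactions(mech)
  stopifnot(interaction >= 1, interaction <= nrow(tab))
  row <- tab[interaction, ]
  if (row$type == "network") {
    mech$T[row$gene_from, row$gene_to] <- 0
  } else {
    idx <- which(mech$couplings$gene == row$gene_from &
                   mech$couplings$target == row$target)[1]
    mech$couplings <- mech$couplings[-idx, ]
  }
  mech
}

#' Serialize / deserialize a developmental mechanism
#'
#' Plain-text format with three sections: a header (gene count, default
#' division rate, gradient gene), an edge list (`source, target, strength`,
#' where the target is a gene `g<k>` or a behavior name), and a per-gene
#' spec table.  Values are written with 17 significant digits so the
#' round-trip is exact.
#'
#' @param mech A `dev_mechanism`.
#' @param path File path.
#' @export
write_mechanism <- function(mech, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("n_genes: %d", mech$n_genes),
    sprintf("default_division_rate: %s", fmt(mech$default_division_rate)),
    sprintf("gradient_gene: %d", mech$gradient_gene),
    "[edges]"), con)
  nz <- which(mech$T != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  if (nrow(nz)) {
    writeLines(sprintf("g%d,g%d,%s", nz[, 1], nz[, 2], fmt(mech$T[nz])), con)
  }
  if (nrow(mech$couplings)) {
    writeLines(sprintf("g%d,%s,%s", mech$couplings$gene,
                       mech$couplings$target, fmt(mech$couplings$strength)),
               con)
  }
  writeLines("[genes]", con)
  gs <- mech$gene_specs
  writeLines(sprintf("g%d,%d,%s,%s", gs$gene, as.integer(gs$diffusible),
                     fmt(gs$diffusion_rate), fmt(gs$degradation_rate)), con)
  invisible(path)
}

#' @rdname write_mechanism
#' @export
read_mechanism <- function(path) {
  ln <- readLines(path)
  hdr <- function(key) sub(paste0("^", key, ": *"), "",
                           grep(paste0("^", key, ":"), ln, value = TRUE)[1])
  n <- as.integer(hdr("n_genes"))
  ddr <- as.numeric(hdr("default_division_rate"))
  ggene <- as.integer(hdr("gradient_gene"))
  ie <- which(ln == "[edges]")
  ig <- which(ln == "[genes]")
  T_mat <- matrix(0, n, n)
  cpl <- tibble::tibble(gene = integer(), target = character(),
                        strength = numeric())
  if (ig > ie + 1) {
    for (row in strsplit(ln[(ie + 1):(ig - 1)], ",")) {
      from <- as.integer(sub("^g", "", row[1]))
      if (grepl("^g[0-9]+$", row[2])) {
        T_mat[from, as.integer(sub("^g", "", row[2]))] <- as.numeric(row[3])
      } else {
        cpl <- dplyr::bind_rows(cpl, tibble::tibble(
          gene = from, target = row[2], strength = as.numeric(row[3])))
      }
    }
  }
  gl <- do.call(rbind, strsplit(ln[(ig + 1):length(ln)], ","))
  gs <- tibble::tibble(
    gene = as.integer(sub("^g", "", gl[, 1])),
    diffusible = gl[, 2] == "1",
    diffusion_rate = as.numeric(gl[, 3]),
    degradation_rate = as.numeric(gl[, 4]))
  gs <- gs[order(gs$gene), ]
  dev_mechanism(T_mat, gs, cpl, default_division_rate = ddr,
                gradient_gene = ggene)
}
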