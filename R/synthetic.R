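# Synthetic study generator: a toy metabolome, decorated test compounds
# spanning a range of Ub values, and toxicity records with a planted
# negative Ub effect concentrated at low potency. Everything is
# deterministic under the seed, so recovery experiments are reproducible.

#' Simulation parameters
#'
#' Defaults emulate the regime the correlation analysis targets: most
#' compounds are non-specific toxins whose log10 EC50 decreases with
#' normalized Ub (slope `beta`), while a minority fraction `q` act through
#' a specific potent mechanism whose potency is independent of Ub. The
#' two-population mixture is the minimal generator of a potency-threshold
#' phenomenon: the Ub signal lives in the low-potency (high EC50)
#' population and is diluted among potent specific toxins.
#'
#' @param n_metabolites Size of the toy metabolome.
#' @param metabolite_max_size Heavy-atom cap of the metabolome space.
#' @param n_compounds Number of test compounds.
#' @param decorations Fragment alphabet grafted onto metabolite scaffolds
#'   (halogens, hydrazine-like N-N, a small ring, a peroxide).
#' @param max_decorations Most decorations per compound.
#' @param p_exotic Fraction of compounds assembled from decoration
#'   fragments alone (no metabolite scaffold), so that the library spans
#'   normalized Ub all the way to 1 — the analogue of test molecules that
#'   are unbiological over their whole extent.
#' @param ub_n Fragment size used for the planted Ub (3 suits the toy
#'   metabolome scale).
#' @param mu0 Baseline log10 EC50 (molar) of non-specific toxins.
#' @param beta Planted slope per unit of normalized Ub (Ub divided by
#'   heavy-atom count); negative.
#' @param sigma Log10 EC50 noise s.d.
#' @param q Fraction of specific-mechanism (potent) compounds.
#' @param mu1 Log10 EC50 of the specific-mechanism population.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `ub_sim_params`.
#' @export
sim_params <- function(n_metabolites = 25L,
                       metabolite_max_size = 6L,
                       n_compounds = 400L,
                       decorations = c("Cl", "F", "Br", "NN", "C1CC1", "OO"),
                       max_decorations = 3L,
                       p_exotic = 0.25,
                       ub_n = 3L,
                       mu0 = -2, beta = -0.8, sigma = 0.5,
                       q = 0.15, mu1 = -6,
                       seed = 1L) {
  stopifnot(sigma > 0, q >= 0, q <= 1, n_metabolites >= 2L,
            n_compounds >= 1L, ub_n >= 2L, p_exotic >= 0, p_exotic <= 1)
  structure(list(
    n_metabolites = as.integer(n_metabolites),
    metabolite_max_size = as.integer(metabolite_max_size),
    n_compounds = as.integer(n_compounds),
    decorations = decorations, max_decorations = as.integer(max_decorations),
    p_exotic = p_exotic,
    ub_n = as.integer(ub_n),
    mu0 = mu0, beta = beta, sigma = sigma, q = q, mu1 = mu1,
    seed = as.integer(seed)
  ), class = "ub_sim_params")
}

# The metabolome space: acyclic CHON molecules with single/double bonds
# and the default instability bans -- a deliberately "biological-looking"
# toy corner of chemical space (no halogens, no peroxide chains).
.metabolome_spec <- function(params) {
  chem_space_spec(elements = c("C", "N", "O"),
                  max_size = params$metabolite_max_size,
                  bond_orders = c(1L, 2L),
                  rings = FALSE,
                  banned = c(default_banned_patterns(), "OO", "NN"))
}

#' Toy metabolome
#'
#' Draws `n_metabolites` distinct molecules uniformly (without
#' replacement) from the enumerated toy metabolome space: acyclic C/N/O
#' molecules of 2 or more heavy atoms with single and double bonds, with
#' peroxide, N-N and the default unstable motifs excluded.
#'
#' @param params A [sim_params()].
#' @return Molecule-set tibble (`id`, `smiles`, `heavy_atoms`),
#'   provenance `"synthetic"`.
#' @export
make_toy_metabolome <- function(params = sim_params()) {
  space <- enumerate_space(.metabolome_spec(params))
  space <- space[space$heavy_atoms >= 2L, ]
  if (params$n_metabolites > nrow(space))
    stop("requested ", params$n_metabolites, " metabolites but the toy ",
         "space only holds ", nrow(space), call. = FALSE)
  idx <- withr::with_seed(params$seed,
    sample.int(nrow(space), params$n_metabolites))
  out <- tibble::tibble(id = sprintf("met%03d", seq_along(idx)),
                        smiles = space$smiles[sort(idx)],
                        heavy_atoms = space$heavy_atoms[sort(idx)])
  attr(out, "provenance") <- "synthetic"
  out
}

# graft one decoration fragment onto a random open-valence atom pair
.graft <- function(g, dec) {
  fg <- free_valences(g)
  open_g <- which(fg >= 1L)
  fd <- free_valences(dec)
  open_d <- which(fd >= 1L)
  if (length(open_g) == 0L || length(open_d) == 0L) return(NULL)
  a <- open_g[sample.int(length(open_g), 1L)]
  d <- open_d[sample.int(length(open_d), 1L)]
  A <- heavy_atoms(g)
  nb <- dec$bond
  if (nrow(nb) > 0L) nb[, 1:2] <- nb[, 1:2] + A
  molgraph(c(g$elem, dec$elem),
           rbind(g$bond, nb, c(a, d + A, 1L)), validate = FALSE)
}

#' Synthetic test compounds
#'
#' Builds a screening-library-like compound set spanning the whole Ub
#' range: most compounds are metabolome scaffolds carrying 0 to
#' `max_decorations` grafted decoration fragments (halogens, N-N, small
#' rings, peroxides), so their unbiological region grows with decoration;
#' a fraction `p_exotic` is assembled from decoration fragments alone,
#' giving molecules that are unbiological over their entire extent
#' (normalized Ub near 1).
#'
#' @param metabolome Output of [make_toy_metabolome()].
#' @param params A [sim_params()].
#' @return Molecule-set tibble (`id`, `smiles`, `heavy_atoms`),
#'   provenance `"synthetic"`.
#' @export
make_test_compounds <- function(metabolome, params = sim_params()) {
  stopifnot(nrow(metabolome) >= 1L)
  scaff <- lapply(metabolome$smiles, parse_structure)
  decs <- lapply(params$decorations, parse_structure)
  out <- withr::with_seed(params$seed + 1L, {
    smiles <- character(params$n_compounds)
    for (i in seq_len(params$n_compounds)) {
      if (stats::runif(1) < params$p_exotic) {
        # wholly exotic: joined decoration fragments, at least 4 atoms;
        # seeded from a multivalent fragment so growth cannot dead-end
        multi <- which(vapply(decs, function(d)
          sum(free_valences(d)) >= 2L, logical(1)))
        if (length(multi) == 0L) multi <- seq_along(decs)
        g <- decs[[multi[sample.int(length(multi), 1L)]]]
        tries <- 0L
        while (heavy_atoms(g) < 4L && tries < 20L) {
          cand <- .graft(g, decs[[sample.int(length(decs), 1L)]])
          if (!is.null(cand)) g <- cand
          tries <- tries + 1L
        }
      } else {
        g <- scaff[[sample.int(length(scaff), 1L)]]
        k <- sample.int(params$max_decorations + 1L, 1L) - 1L
        for (j in seq_len(k)) {
          cand <- .graft(g, decs[[sample.int(length(decs), 1L)]])
          if (!is.null(cand)) g <- cand
        }
      }
      smiles[i] <- mol_to_smiles(g)
    }
    smiles
  })
  res <- tibble::tibble(id = sprintf("cmp%04d", seq_along(out)),
                        smiles = out)
  attr(res, "provenance") <- "synthetic"
  res
}

#' Simulate toxicity with a planted low-potency Ub effect
#'
#' With probability `q` a compound is a specific-mechanism toxin with
#' `log10 EC50 ~ Normal(mu1, sigma)` independent of Ub; otherwise
#' `log10 EC50 ~ Normal(mu0 + beta * Ub/heavy_atoms, sigma)`.
#'
#' @param compounds Molecule-set tibble (`id`, `smiles`).
#' @param ub Ub scores aligned with `compounds`: a numeric vector or a
#'   [ub_table()] result containing `ub<n>` and `heavy_atoms` columns.
#' @param params A [sim_params()].
#' @return Toxicity-record tibble: `id`, `smiles`, `endpoint`,
#'   `log_ec50`, `mechanism` (`"nonspecific"`/`"specific"`).
#' @export
simulate_toxicity <- function(compounds, ub, params = sim_params()) {
  if (is.data.frame(ub)) {
    col <- paste0("ub", params$ub_n)
    stopifnot(col %in% names(ub), "heavy_atoms" %in% names(ub))
    ubv <- ub[[col]][match(compounds$id, ub$id)]
    ha <- ub$heavy_atoms[match(compounds$id, ub$id)]
  } else {
    ubv <- as.numeric(ub)
    ha <- vapply(lapply(compounds$smiles, parse_structure), heavy_atoms,
                 integer(1))
  }
  stopifnot(length(ubv) == nrow(compounds))
  ub_norm <- ubv / ha
  withr::with_seed(params$seed + 2L, {
    specific <- stats::runif(nrow(compounds)) < params$q
    mu <- ifelse(specific, params$mu1, params$mu0 + params$beta * ub_norm)
    log_ec50 <- stats::rnorm(nrow(compounds), mu, params$sigma)
    tibble::tibble(id = compounds$id, smiles = compounds$smiles,
                   endpoint = "synthetic growth inhibition",
                   log_ec50 = log_ec50,
                   mechanism = ifelse(specific, "specific", "nonspecific"))
  })
}

#' Run a full synthetic study
#'
#' Convenience driver: metabolome, compounds, Ub scores at `params$ub_n`,
#' and toxicity records, all from one seed.
#'
#' @param params A [sim_params()].
#' @return A list with `metabolome`, `compounds`, `ub` and `toxicity`.
#' @export
simulate_study <- function(params = sim_params()) {
  metabolome <- make_toy_metabolome(params)
  compounds <- make_test_compounds(metabolome, params)
  ub <- ub_table(compounds, metabolome, ns = params$ub_n)
  toxicity <- simulate_toxicity(compounds, ub, params)
  list(metabolome = metabolome, compounds = compounds, ub = ub,
       toxicity = toxicity, params = params)
}
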