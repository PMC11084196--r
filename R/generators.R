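#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic ligand-table, binding-site and
#' sensorgram generators into one validated object. The defaults describe
#' the study conditions the rest of the package is exercised under: a
#' DrugBank-scale table of 1000 candidate ligands with per-filter pass
#' fractions of 0.68 (so roughly 100 survive the six-stage cascade), 100
#' predicted binding sites planted in five sequence-separated HSA regions,
#' and sensorgrams at the five analyte concentrations 2.5--40 uM with 1 RU
#' of additive Gaussian noise.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_ligands Number of ligand records to generate.
#' @param filter_pass_fractions Named numeric vector in `[0, 1]` giving, for
#'   each filter stage (`mass`, `solubility`, `bbb`, `plasma`, `references`,
#'   `fatty_acid`), the marginal probability that a record passes that stage.
#' @param n_clusters Number of planted binding-site clusters.
#' @param sites_per_cluster Number of binding sites generated per cluster.
#' @param site_jitter Number of residues randomly removed from and added to
#'   each site relative to its cluster archetype.
#' @param noise_sd Standard deviation (response units) of the Gaussian noise
#'   added to generated sensorgrams.
#' @param analyte_concs Analyte (HSA) concentrations, in molar, at which
#'   sensorgrams are generated.
#'
#' @return An object of class `generator_config`.
#' @seealso [gen_ligand_table()], [gen_binding_sites()], [gen_sensorgram()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 42, n_ligands = 50)
#' nrow(gen_ligand_table(cfg))
generator_config <- function(seed = 1L,
                             n_ligands = 1000L,
                             filter_pass_fractions = c(
                               mass = 0.68, solubility = 0.68, bbb = 0.68,
                               plasma = 0.68, references = 0.68,
                               fatty_acid = 0.68
                             ),
                             n_clusters = 5L,
                             sites_per_cluster = 20L,
                             site_jitter = 2L,
                             noise_sd = 1,
                             analyte_concs = c(2.5, 5, 10, 20, 40) * 1e-6) {
  seed <- check_count(seed, "seed")
  n_ligands <- check_count(n_ligands, "n_ligands")
  n_clusters <- check_count(n_clusters, "n_clusters")
  sites_per_cluster <- check_count(sites_per_cluster, "sites_per_cluster")
  site_jitter <- check_count(site_jitter, "site_jitter")
  check_number(noise_sd, "noise_sd", min = 0)
  stage_names <- c("mass", "solubility", "bbb", "plasma", "references",
                   "fatty_acid")
  if (is.null(names(filter_pass_fractions)) ||
      !all(stage_names %in% names(filter_pass_fractions))) {
    stopf("'filter_pass_fractions' must be named with: %s",
          paste(stage_names, collapse = ", "))
  }
  for (nm in stage_names) {
    check_fraction(filter_pass_fractions[[nm]],
                   paste0("filter_pass_fractions$", nm))
  }
  if (length(analyte_concs) < 1L || any(analyte_concs < 0)) {
    stopf("'analyte_concs' must be non-negative molar concentrations")
  }
  structure(
    list(
      seed = seed, n_ligands = n_ligands,
      filter_pass_fractions = filter_pass_fractions[stage_names],
      n_clusters = n_clusters, sites_per_cluster = sites_per_cluster,
      site_jitter = site_jitter, noise_sd = noise_sd,
      analyte_concs = as.numeric(analyte_concs)
    ),
    class = "generator_config"
  )
}

# Draw n values that land inside the filter's pass region with probability
# p, from documented marginals: for each record an independent pass/fail
# coin is flipped, then the value is drawn from the marginal conditioned on
# the chosen side of the threshold. This makes per-filter survivor counts
# exactly Binomial(n, p), so tests can dial expected counts analytically.
sample_two_sided <- function(n, p, rpass, rfail) {
  pass <- runif(n) < p
  out <- numeric(n)
  if (any(pass)) out[pass] <- rpass(sum(pass))
  if (any(!pass)) out[!pass] <- rfail(sum(!pass))
  list(value = out, pass = pass)
}

log_uniform <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

#' Generate a synthetic ligand table
#'
#' Emulates a DrugBank-like candidate table with the six attributes the
#' screening cascade filters on. Each attribute is sampled independently;
#' the probability of passing each filter equals the configured
#' `filter_pass_fractions` entry exactly (per-record Bernoulli), with
#' attribute values drawn from documented marginals conditioned on the
#' pass/fail side of the threshold: mass uniform on `[50, 1200]` Da (so both
#' tails of the mass window are exercised), solubility and plasma
#' concentration log-uniform, BBB penetration uniform in percent, reference
#' counts Poisson-shifted.
#'
#' @param cfg A [generator_config()].
#' @return A `data.frame` with columns `id`, `name`, `mass` (Da),
#'   `solubility` (uM), `bbb_penetration` (percent), `plasma_conc` (nM),
#'   `ad_refs` (count), `is_fatty_acid` (logical).
#' @export
gen_ligand_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_ligands
  p <- cfg$filter_pass_fractions
  with_seed(cfg$seed, {
    mass <- sample_two_sided(
      n, p[["mass"]],
      rpass = function(m) runif(m, 100, 900),
      rfail = function(m) {
        # fail mass: below 100 Da or above 900 Da, widths 50 and 300
        low <- runif(m) < 50 / 350
        ifelse(low, runif(m, 50, 100), runif(m, 900, 1200))
      }
    )
    sol <- sample_two_sided(
      n, p[["solubility"]],
      rpass = function(m) log_uniform(m, 1, 1e5),      # uM, above threshold
      rfail = function(m) log_uniform(m, 1e-3, 1)
    )
    bbb <- sample_two_sided(
      n, p[["bbb"]],
      rpass = function(m) runif(m, 50, 100),
      rfail = function(m) runif(m, 0, 50)
    )
    plasma <- sample_two_sided(
      n, p[["plasma"]],
      rpass = function(m) log_uniform(m, 0.5, 1e4),    # nM
      rfail = function(m) log_uniform(m, 1e-4, 0.5)
    )
    refs <- sample_two_sided(
      n, p[["references"]],
      rpass = function(m) 2L + rpois(m, 5),
      rfail = function(m) sample(0:1, m, replace = TRUE)
    )
    fa_pass <- runif(n) < p[["fatty_acid"]]            # pass = not a FA
    data.frame(
      id = sprintf("SYN%05d", seq_len(n)),
      name = sprintf("compound_%05d", seq_len(n)),
      mass = mass$value,
      solubility = sol$value,
      bbb_penetration = bbb$value,
      plasma_conc = plasma$value,
      ad_refs = as.integer(refs$value),
      is_fatty_acid = !fa_pass,
      stringsAsFactors = FALSE
    )
  })
}

# Three-letter amino-acid codes; residue identities in synthetic sites come
# from a fixed residue-number -> code map (no real HSA sequence is shipped),
# so a residue number always carries the same synthetic identity.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

aa_for_residue <- function(number) AA3[(number * 7L) %% 20L + 1L]

#' Construct a binding site
#'
#' A predicted ligand binding site on HSA: a set of residues (number +
#' amino-acid code) in the numbering of PDB entry 1UOR chain A (1--585).
#'
#' @param ligand_id Opaque ligand identifier.
#' @param numbers Integer residue numbers, unique, in `[1, 585]`.
#' @param aa Amino-acid codes, same length as `numbers`; defaults to the
#'   package's synthetic residue-number map.
#' @param true_cluster Optional hidden generator label, used only by
#'   cluster-recovery tests, never by the clustering itself.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(ligand_id, numbers, aa = aa_for_residue(numbers),
                         true_cluster = NULL) {
  numbers <- as.integer(numbers)
  if (anyDuplicated(numbers)) {
    stopf("binding site '%s' has duplicated residue numbers", ligand_id)
  }
  if (length(numbers) && (min(numbers) < 1L || max(numbers) > 585L)) {
    stopf("residue numbers must lie in [1, 585] (PDB 1UOR chain A)")
  }
  structure(
    list(
      ligand_id = as.character(ligand_id),
      residues = data.frame(number = numbers, aa = as.character(aa),
                            stringsAsFactors = FALSE),
      true_cluster = true_cluster
    ),
    class = "binding_site"
  )
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("Binding site for ligand '%s': %d residues (1UOR chain A)\n",
              x$ligand_id, nrow(x$residues)))
  cat(" ", paste0(x$residues$aa, x$residues$number, collapse = ", "), "\n")
  invisible(x)
}

# Default archetype centres: one representative key-residue region per
# cluster reported for HSA (subdomains IB, IIA/IIB, IIIA ...), picked at
# least 50 residues apart in sequence so planted partitions are well-posed
# for a residue-number-series distance.
default_archetype_centers <- function(k) {
  base <- c(117L, 191L, 292L, 447L, 525L)
  if (k <= length(base)) return(base[seq_len(k)])
  extra <- as.integer(seq(30L, 560L, length.out = k))
  sort(unique(c(base, extra)))[seq_len(k)]
}

#' Generate synthetic binding sites with planted cluster structure
#'
#' Plants `n_clusters` archetype sites in distinct regions of the HSA
#' sequence and emits `sites_per_cluster` jittered copies of each:
#' `site_jitter` residues are removed at random and the same number of new
#' residues are added near the archetype centre. Each site carries its
#' hidden `true_cluster` label for recovery tests; the clustering code never
#' reads it.
#'
#' @param cfg A [generator_config()].
#' @param archetype_size Residues per archetype site.
#' @param centers Optional integer vector of archetype centre residues
#'   (length `n_clusters`); defaults to sequence-separated HSA regions.
#' @return A list of [binding_site()] objects, length
#'   `n_clusters * sites_per_cluster`.
#' @export
gen_binding_sites <- function(cfg, archetype_size = 9L, centers = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  archetype_size <- check_count(archetype_size, "archetype_size", min = 1L)
  if (cfg$site_jitter > archetype_size) {
    stopf("site_jitter (%d) exceeds archetype size (%d)",
          cfg$site_jitter, archetype_size)
  }
  if (is.null(centers)) centers <- default_archetype_centers(cfg$n_clusters)
  if (length(centers) != cfg$n_clusters) {
    stopf("need %d archetype centers, got %d", cfg$n_clusters,
          length(centers))
  }
  half <- (archetype_size - 1L) %/% 2L
  archetypes <- lapply(centers, function(ctr) {
    res <- ctr + seq(-half, length.out = archetype_size)
    pmin(pmax(res, 1L), 585L)
  })
  with_seed(cfg$seed, {
    sites <- vector("list", cfg$n_clusters * cfg$sites_per_cluster)
    idx <- 0L
    for (g in seq_len(cfg$n_clusters)) {
      for (j in seq_len(cfg$sites_per_cluster)) {
        res <- archetypes[[g]]
        if (cfg$site_jitter > 0L) {
          drop <- sample(seq_along(res), cfg$site_jitter)
          res <- res[-drop]
          pool <- setdiff(
            pmin(pmax(centers[g] + (-15L:15L), 1L), 585L), res)
          res <- c(res, sample(pool, cfg$site_jitter))
        }
        idx <- idx + 1L
        sites[[idx]] <- binding_site(
          ligand_id = sprintf("SYN%05d", idx),
          numbers = sort(unique(res)),
          true_cluster = g
        )
      }
    }
    sites
  })
}

#' Generate a noisy synthetic sensorgram
#'
#' Evaluates the two-site (heterogeneous-ligand) closed-form response via
#' [simulate_sensorgram()] and adds pointwise Gaussian noise. With
#' `noise_sd = 0` the output is bit-identical to the noiseless simulator.
#'
#' @param kp A [kinetic_params()] object.
#' @param rmax1,rmax2 Response capacity (RU) of the two site classes.
#' @param conc Analyte concentration, molar.
#' @param t_assoc Association-phase duration, seconds.
#' @param t_dissoc Dissociation-phase duration, seconds.
#' @param dt Sampling interval, seconds.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed Optional integer seed for the noise.
#' @return A [sensorgram()] object.
#' @export
gen_sensorgram <- function(kp, rmax1, rmax2, conc,
                           t_assoc = 300, t_dissoc = 2400, dt = 1,
                           noise_sd = 0, seed = NULL) {
  check_number(t_assoc, "t_assoc", min = 0, strict_min = TRUE)
  check_number(t_dissoc, "t_dissoc", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  sg <- simulate_sensorgram(kp, rmax1, rmax2, conc, times, t_assoc)
  if (noise_sd > 0) {
    sg$response <- sg$response +
      with_seed(seed, rnorm(length(times), sd = noise_sd))
  }
  attr(sg, "noise_sd") <- noise_sd
  sg
}
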