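# Synthetic two-arm longitudinal infant cohort generator.
#
# The generator emulates the structure of an HMO-supplementation trial in
# formula-fed infants: ~130 infants enrolled between 2 weeks and 6 months of
# age, randomised 1:1 to a control or test (HMO-supplemented) formula,
# sampled at enrollment (V0), +30 d (V1), +90 d (V3) and at 365 d of age
# (V6). Each infant follows a latent forward-only progression through five
# fecal community types (FCT1..FCT5) with exponential per-stage waiting
# times; the test arm's transition hazards are multiplied by a hazard ratio
# (< 1 slows maturation) from enrollment onward. Genus counts are
# Dirichlet-multinomial draws from the latent FCT's alpha vector; metabolite
# and bile-acid concentrations are log-normal with FCT-, arm- and
# visit-dependent location parameters; KO relative abundances are linear
# mixtures of FCT identity plus log-normal noise.

DEFAULT_GENERA <- c(
  "Escherichia", "Klebsiella", "Enterobacter", "Veillonella",
  "Streptococcus", "Staphylococcus", "Bifidobacterium", "Lactobacillus",
  "Collinsella", "Enterococcus", "Clostridium", "Bacteroides",
  "Lachnoclostridium", "Blautia", "Ruminococcus", "Faecalibacterium",
  "Anaerostipes", "Roseburia", "Eubacterium", "Dorea", "Akkermansia",
  "Parabacteroides", "Alistipes", "Prevotella", "Coprococcus", "Dialister",
  "Megasphaera", "Oscillibacter", "Fusicatenibacter", "Subdoligranulum")

# Mean genus compositions of the five latent community types. Dominant
# genera per type follow the classic infant maturation sequence:
# proteobacteria (FCT1) -> bifidobacteria (FCT2) -> mixed firmicutes with
# Lachnoclostridium/Bacteroides (FCT3) -> diverse firmicutes (FCT4) ->
# Faecalibacterium-rich adult-like (FCT5).
default_fct_profiles <- function() {
  g <- DEFAULT_GENERA
  prof <- matrix(0, nrow = 5L, ncol = length(g), dimnames = list(NULL, g))
  set_p <- function(k, ...) {
    v <- c(...)
    prof[k, names(v)] <<- v
  }
  set_p(1L, Escherichia = 0.30, Klebsiella = 0.15, Enterobacter = 0.08,
        Veillonella = 0.08, Streptococcus = 0.07, Staphylococcus = 0.05,
        Bifidobacterium = 0.10, Enterococcus = 0.06, Lactobacillus = 0.03)
  set_p(2L, Bifidobacterium = 0.45, Collinsella = 0.09, Lactobacillus = 0.06,
        Veillonella = 0.08, Streptococcus = 0.06, Escherichia = 0.07,
        Enterococcus = 0.03)
  set_p(3L, Lachnoclostridium = 0.20, Bacteroides = 0.14, Blautia = 0.10,
        Clostridium = 0.08, Bifidobacterium = 0.08, Ruminococcus = 0.06,
        Veillonella = 0.05, Parabacteroides = 0.04)
  set_p(4L, Blautia = 0.15, Ruminococcus = 0.12, Eubacterium = 0.10,
        Dorea = 0.08, Coprococcus = 0.08, Anaerostipes = 0.07,
        Bacteroides = 0.08, Fusicatenibacter = 0.05, Dialister = 0.03)
  set_p(5L, Faecalibacterium = 0.22, Ruminococcus = 0.10, Roseburia = 0.10,
        Subdoligranulum = 0.08, Oscillibacter = 0.06, Alistipes = 0.06,
        Bacteroides = 0.08, Akkermansia = 0.05, Prevotella = 0.04,
        Eubacterium = 0.04)
  # Spread the remaining mass uniformly so every genus can appear anywhere.
  rest <- 1 - rowSums(prof)
  prof + rest / ncol(prof)
}

#' Names of the 43-analyte fecal bile-acid panel
#'
#' Standard abbreviations: unconjugated primary/secondary bile acids plus
#' their glycine (G-) and taurine (T-) conjugates.
#'
#' @return Character vector of 43 analyte names.
#' @export
bile_acid_panel <- function() {
  c(# unconjugated (21)
    "CA", "CDCA", "DCA", "LCA", "UDCA", "HDCA", "HCA", "DHCA",
    "7-ketoDCA", "7-ketoLCA", "12-ketoLCA", "6,7-diketoLCA",
    "isoLCA", "alloLCA", "isoDCA", "NorCA", "NorDCA",
    "alphaMCA", "betaMCA", "omegaMCA", "UCA",
    # oxo forms (3)
    "3-oxoCA", "3-oxoCDCA", "3-oxoDCA",
    # glycine conjugates (8)
    "GCA", "GCDCA", "GDCA", "GLCA", "GUDCA", "GHDCA", "GHCA", "GDHCA",
    # taurine conjugates (11)
    "TCA", "TCDCA", "TDCA", "TLCA", "TUDCA", "THDCA", "THCA", "TDHCA",
    "TalphaMCA", "TbetaMCA", "TomegaMCA")
}

# Log-normal location/scale specification for the non-bile-acid metabolite
# panel. Columns: base location (nmol/g, FCT1 / V0 / control), log-scale
# slope per FCT step, log-scale arm-and-visit offsets, and sdlog.
# Fusel acids (amino-acid fermentation products) rise with community
# maturity and are suppressed in the test arm at V3/V6; 2'-FL traces decay
# with visit in the control arm and are strongly elevated under
# supplementation from V1 on.
default_metabolite_spec <- function() {
  m <- function(name, base, slope = 0, sd = 0.6,
                c1 = 0, c3 = 0, c6 = 0, t1 = 0, t3 = 0, t6 = 0) {
    data.frame(metabolite = name, base = base, fct_slope = slope, sdlog = sd,
               off_V1_control = c1, off_V3_control = c3, off_V6_control = c6,
               off_V1_test = t1, off_V3_test = t3, off_V6_test = t6,
               stringsAsFactors = FALSE)
  }
  rbind(
    # 2'-FL: control traces 86 -> 64 -> ~15 nmol/g; test arm spiked after V0.
    m("2'-FL", 86, sd = 0.8,
      c1 = log(64 / 86), c3 = log(15 / 86), c6 = log(15 / 86),
      t1 = log(1200 / 86), t3 = log(300 / 86), t6 = log(37 / 86)),
    m("LNnT", 30, sd = 0.8,
      c1 = log(0.7), c3 = log(0.4), c6 = log(0.4),
      t1 = log(8), t3 = log(4), t6 = log(1.5)),
    m("Lactose", 5000, sd = 0.7, t3 = log(1.8)),
    m("Fucose", 120, sd = 0.7),
    m("Acetic acid", 25000, slope = 0.05, sd = 0.5,
      c1 = log(0.7), c3 = log(0.75), c6 = log(0.8)),
    m("Propionic acid", 4000, slope = 0.30, sd = 0.5),
    m("Butyric acid", 2000, slope = 0.40, sd = 0.6),
    m("Valeric acid", 300, slope = 0.35, sd = 0.6),
    m("Lactic acid", 3000, slope = -0.25, sd = 0.7),
    # Ehrlich-pathway fusel acids and related catabolites.
    m("Isobutyric acid", 500, slope = 0.35, sd = 0.6,
      t3 = log(0.44), t6 = log(0.36)),
    m("Isovaleric acid", 400, slope = 0.35, sd = 0.6,
      t3 = log(0.28), t6 = log(0.44)),
    m("Phenylacetic acid", 250, slope = 0.35, sd = 0.7,
      t3 = log(0.24), t6 = log(0.34)),
    m("2-Hydroxyphenylacetic acid", 60, slope = 0.30, sd = 0.7,
      t3 = log(0.31), t6 = log(0.60)),
    m("3-Hydroxyphenylacetic acid", 80, slope = 0.30, sd = 0.7,
      t3 = log(0.24), t6 = log(0.77)),
    m("4-Cresol sulfate", 150, slope = 0.30, sd = 0.7,
      t3 = log(0.28), t6 = log(0.40)),
    m("Hydrocinnamic acid", 40, slope = 0.30, sd = 0.7,
      t3 = log(0.21), t6 = log(0.25)),
    m("L-Phenylalanine", 900, slope = 0.10, sd = 0.5, t6 = log(0.41)),
    m("Pimelic acid", 30, slope = 0.20, sd = 0.6, t6 = log(0.57)),
    m("Hydroxybenzoic acid", 25, slope = 0.10, sd = 0.7, t6 = log(2.3)),
    m("L-Leucine", 700, slope = 0.05, sd = 0.5),
    m("L-Valine", 650, slope = 0.05, sd = 0.5))
}

# Bile-acid panel specification, same columns as default_metabolite_spec().
# Conjugated analytes dominate the immature gut; bile-salt-hydrolase
# activity grows with community maturity, so unconjugated analytes rise
# with FCT index. The control arm loses deconjugation capacity after
# baseline (negative visit offsets on unconjugated analytes) while the test
# arm maintains it, mirroring a bifidobacteria-sustained BSH activity.
default_bile_acid_spec <- function() {
  panel <- bile_acid_panel()
  conj <- grepl("^(G|T)[A-Za-z]|^Talpha|^Tbeta|^Tomega", panel) &
    !panel %in% c("UDCA", "UCA")
  conj <- startsWith(panel, "G") | startsWith(panel, "T")
  base <- ifelse(conj, 600, 150)
  # dominant physiological analytes get higher baselines
  base[panel %in% c("GCA", "TCA", "GCDCA", "TCDCA")] <- 2000
  base[panel %in% c("CA", "CDCA")] <- 500
  base[panel %in% c("DCA", "LCA", "DHCA")] <- 80
  slope <- ifelse(conj, -0.10, 0.10)
  decline <- ifelse(conj, 0, -0.8)  # control arm loses deconjugation
  spec <- data.frame(
    metabolite = panel, base = base, fct_slope = slope, sdlog = 0.7,
    off_V1_control = decline, off_V3_control = decline,
    off_V6_control = decline,
    off_V1_test = 0, off_V3_test = 0, off_V6_test = 0,
    stringsAsFactors = FALSE)
  # dehydrocholic acid is specifically depleted in the test arm at V3
  i <- spec$metabolite == "DHCA"
  spec$off_V3_test[i] <- log(0.51)
  spec
}

# KO panel: a bile-salt hydrolase (K01442) plus amino-acid catabolism
# enzymes; each KO loads on one latent FCT so KO abundance tracks community
# maturity.
default_ko_spec <- function(n_fct = 5L) {
  ko_ids <- c("K01442", "K00826", "K00382", "K01652", "K00016", "K00101",
              "K00161", "K00162", "K00627", "K01580", "K01667", "K04103",
              "K00274", "K00128", "K01905", "K00929", "K00169", "K00170",
              "K03778", "K13745")
  loading <- matrix(0.2, nrow = n_fct, ncol = length(ko_ids),
                    dimnames = list(NULL, ko_ids))
  for (j in seq_along(ko_ids)) {
    loading[((j - 1L) %% n_fct) + 1L, j] <- 1.2
  }
  # BSH loads on late, adult-like communities
  loading[, "K01442"] <- seq(0.1, 1.2, length.out = n_fct)
  list(ko_ids = ko_ids, loading = loading, noise_sdlog = 0.4)
}

#' Configuration of the synthetic cohort generator
#'
#' Builds a validated configuration object for [generate_cohort()]. Defaults
#' emulate a two-arm HMO-supplementation trial: 132 infants enrolled
#' between 14 and 180 days of age, 1:1 randomisation, stratum cutoff at 90
#' days, five latent community types over 30 genera, a treatment hazard
#' ratio of 0.56 on FCT progression, negative-binomial library sizes around
#' 20,000 reads, and linked metabolite / 43-analyte bile-acid / KO panels.
#'
#' @param n_infants Number of infants.
#' @param arm_ratio Proportion randomised to the test arm, in (0, 1).
#' @param enroll_age_range Enrollment age range in days.
#' @param stratum_cutoff Stratum cutoff age in days.
#' @param n_fct Number of latent community types.
#' @param alpha_matrix `n_fct` x taxa matrix of positive Dirichlet
#'   parameters (rows are per-FCT alpha vectors).
#' @param base_hazards Per-transition progression rates (1/day), length
#'   `n_fct - 1`.
#' @param treatment_hazard_ratio Multiplier on the transition hazards in the
#'   test arm from enrollment onward; values below 1 slow maturation.
#' @param depth_mean,depth_size Mean and dispersion (size) of the
#'   negative-binomial library-size distribution.
#' @param metabolite_spec,bile_acid_spec Data frames of per-metabolite
#'   log-normal locations/scales with FCT slopes and per-arm visit offsets;
#'   see `fctomics:::default_metabolite_spec()` for the column layout.
#' @param ko_spec List with `ko_ids`, an FCT x KO `loading` matrix and
#'   `noise_sdlog`.
#' @param dropout_prob Probability that each post-baseline visit is missed.
#' @param seed Default master seed recorded in the configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_infants = 132L,
                          arm_ratio = 0.5,
                          enroll_age_range = c(14, 180),
                          stratum_cutoff = 90,
                          n_fct = 5L,
                          alpha_matrix = NULL,
                          base_hazards = c(1 / 60, 1 / 90, 1 / 120, 1 / 150),
                          treatment_hazard_ratio = 0.56,
                          depth_mean = 20000,
                          depth_size = 10,
                          metabolite_spec = default_metabolite_spec(),
                          bile_acid_spec = default_bile_acid_spec(),
                          ko_spec = default_ko_spec(n_fct),
                          dropout_prob = 0.10,
                          seed = 1L) {
  if (is.null(alpha_matrix)) {
    if (n_fct != 5L) stop("supply `alpha_matrix` when n_fct != 5")
    alpha_matrix <- default_fct_profiles() * 40  # precision 40
  }
  cfg <- list(n_infants = as.integer(n_infants), arm_ratio = arm_ratio,
              enroll_age_range = enroll_age_range,
              stratum_cutoff = stratum_cutoff, n_fct = as.integer(n_fct),
              alpha_matrix = alpha_matrix, base_hazards = base_hazards,
              treatment_hazard_ratio = treatment_hazard_ratio,
              depth_mean = depth_mean, depth_size = depth_size,
              metabolite_spec = metabolite_spec,
              bile_acid_spec = bile_acid_spec, ko_spec = ko_spec,
              dropout_prob = dropout_prob, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid configuration field `%s`: %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_infants < 1L) fail("n_infants", "must be at least 1")
  if (cfg$arm_ratio <= 0 || cfg$arm_ratio >= 1) fail("arm_ratio", "must be in (0,1)")
  if (cfg$n_fct < 2L) fail("n_fct", "must be at least 2")
  if (!is.matrix(cfg$alpha_matrix) || nrow(cfg$alpha_matrix) != cfg$n_fct) {
    fail("alpha_matrix", "must be an n_fct x taxa matrix")
  }
  if (any(cfg$alpha_matrix <= 0)) fail("alpha_matrix", "entries must be > 0")
  if (length(cfg$base_hazards) != cfg$n_fct - 1L) {
    fail("base_hazards", "needs one rate per forward transition")
  }
  if (any(cfg$base_hazards < 0)) fail("base_hazards", "rates must be >= 0")
  if (cfg$treatment_hazard_ratio <= 0) {
    fail("treatment_hazard_ratio", "must be > 0")
  }
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1) {
    fail("dropout_prob", "must be in [0,1)")
  }
  if (any(cfg$metabolite_spec$sdlog <= 0) || any(cfg$bile_acid_spec$sdlog <= 0)) {
    fail("metabolite_spec", "sdlog scales must be > 0")
  }
  if (any(cfg$metabolite_spec$base <= 0) || any(cfg$bile_acid_spec$base <= 0)) {
    fail("metabolite_spec", "base locations must be > 0")
  }
  if (cfg$depth_mean <= 0 || cfg$depth_size <= 0) {
    fail("depth_dist", "mean and size must be > 0")
  }
  cfg
}

#' Simulate one infant's latent community-type trajectory
#'
#' Forward-only jump process FCT1 -> ... -> FCTn with exponential per-stage
#' waiting times starting at birth. In the test arm, each hazard is
#' multiplied by `treatment_hazard_ratio` from the enrollment age onward
#' (piecewise-constant hazard; the memoryless property makes the switch a
#' simple redraw of the residual waiting time).
#'
#' @param enroll_age Enrollment age in days (treatment start).
#' @param arm `"control"` or `"test"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `age` (transition age in days, first
#'   row age 0) and `fct` (state entered at that age).
#' @export
simulate_fct_trajectory <- function(enroll_age, arm, config, seed = 1L) {
  stopifnot(enroll_age >= 0)
  hr <- if (arm == "test") config$treatment_hazard_ratio else 1
  with_seed(seed, {
    ages <- 0
    states <- 1L
    age <- 0
    for (k in seq_len(config$n_fct - 1L)) {
      rate <- config$base_hazards[k]
      if (rate <= 0) break
      wait <- stats::rexp(1L, rate)
      if (hr != 1 && age + wait > enroll_age) {
        if (age >= enroll_age) {
          wait <- stats::rexp(1L, rate * hr)
        } else {
          # clock crosses the treatment start: survive to enrollment at the
          # base rate, then redraw the residual at the treated rate
          wait <- (enroll_age - age) + stats::rexp(1L, rate * hr)
        }
      }
      age <- age + wait
      ages <- c(ages, age)
      states <- c(states, k + 1L)
    }
  })
  data.frame(age = ages, fct = states)
}

# Latent state at a given age from a trajectory table.
fct_at_age <- function(trajectory, age) {
  trajectory$fct[max(which(trajectory$age <= age))]
}

#' Draw a Dirichlet-multinomial genus count vector
#'
#' @param fct_label Latent community type index in `1..n_fct`.
#' @param depth Total read count to distribute.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `depth`.
#' @export
draw_genus_counts <- function(fct_label, depth, config, seed = 1L) {
  if (!(fct_label %in% seq_len(config$n_fct))) {
    stop("unknown fct_label: ", fct_label)
  }
  stopifnot(depth > 0)
  alpha <- config$alpha_matrix[fct_label, ]
  with_seed(seed, {
    p <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    p <- p / sum(p)
    counts <- drop(stats::rmultinom(1L, size = depth, prob = p))
  })
  names(counts) <- colnames(config$alpha_matrix)
  counts
}

#' Draw a metabolite + bile-acid concentration vector
#'
#' Concentrations (nmol/g) are log-normal with location
#' `log(base) + fct_slope * (fct - 1) + offset(arm, visit)` per analyte.
#'
#' @inheritParams draw_genus_counts
#' @param arm `"control"` or `"test"`.
#' @param visit Visit label in `V0`, `V1`, `V3`, `V6` (arm/visit offsets
#'   apply only after baseline).
#' @return Named numeric vector over the metabolite panel followed by the
#'   43-analyte bile-acid panel.
#' @export
draw_metabolome <- function(fct_label, arm, config, visit = "V0", seed = 1L) {
  if (!(fct_label %in% seq_len(config$n_fct))) {
    stop("unknown fct_label: ", fct_label)
  }
  spec <- rbind(config$metabolite_spec, config$bile_acid_spec)
  off <- rep(0, nrow(spec))
  if (visit %in% c("V1", "V3", "V6")) {
    col <- sprintf("off_%s_%s", visit, arm)
    off <- spec[[col]]
  }
  meanlog <- log(spec$base) + spec$fct_slope * (fct_label - 1L) + off
  with_seed(seed, {
    conc <- stats::rlnorm(nrow(spec), meanlog = meanlog, sdlog = spec$sdlog)
  })
  names(conc) <- spec$metabolite
  conc
}

# KO relative abundances for one sample: loading row of the latent FCT
# perturbed by log-normal noise, normalised to sum 1.
draw_ko <- function(fct_label, config, seed = 1L) {
  ks <- config$ko_spec
  with_seed(seed, {
    raw <- ks$loading[fct_label, ] *
      stats::rlnorm(length(ks$ko_ids), 0, ks$noise_sdlog)
  })
  raw / sum(raw)
}

#' Generate a synthetic two-arm longitudinal infant cohort
#'
#' Simulates infants, their latent FCT trajectories, visit schedules
#' (V0 = enrollment, V1 = +30 d, V3 = +90 d, V6 = 365 d of age, minus
#' dropouts) and the linked genus-count, metabolite/bile-acid and KO tables.
#' Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; defaults to the seed recorded in `config`.
#' @return A list of class `synthetic_cohort` with elements `metadata`
#'   (sample table), `counts` (samples x genera integer matrix),
#'   `metabolites`, `ko`, `truth_fct` (named latent labels) and
#'   `truth_params` (the generating configuration).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  config <- validate_cohort_config(config)
  n <- config$n_infants
  infant_ids <- sprintf("I%03d", seq_len(n))

  enroll <- with_seed(child_seed(seed, "enroll"), {
    list(age = round(stats::runif(n, config$enroll_age_range[1],
                                  config$enroll_age_range[2])),
         arm = ifelse(stats::runif(n) < config$arm_ratio, "test", "control"))
  })

  meta <- list()
  truth <- list()
  counts <- list()
  mtb <- list()
  ko <- list()
  for (i in seq_len(n)) {
    traj <- simulate_fct_trajectory(enroll$age[i], enroll$arm[i], config,
                                    seed = child_seed(seed, paste0("traj", i)))
    visit_age <- c(V0 = enroll$age[i], V1 = enroll$age[i] + 30,
                   V3 = enroll$age[i] + 90, V6 = 365)
    keep <- c(TRUE, with_seed(child_seed(seed, paste0("drop", i)),
                              stats::runif(3) >= config$dropout_prob))
    for (v in names(visit_age)[keep]) {
      sid <- sprintf("%s_%s", infant_ids[i], v)
      age <- visit_age[[v]]
      fct <- fct_at_age(traj, age)
      depth <- with_seed(child_seed(seed, paste0("depth", sid)), {
        max(500L, stats::rnbinom(1L, mu = config$depth_mean,
                                 size = config$depth_size))
      })
      meta[[sid]] <- data.frame(
        sample_id = sid, infant_id = infant_ids[i], visit = v, age = age,
        arm = enroll$arm[i],
        stratum = assign_cohort(enroll$age[i], config$stratum_cutoff),
        stringsAsFactors = FALSE)
      truth[[sid]] <- fct
      counts[[sid]] <- draw_genus_counts(fct, depth, config,
                                         seed = child_seed(seed, paste0("cnt", sid)))
      mtb[[sid]] <- draw_metabolome(fct, enroll$arm[i], config, visit = v,
                                    seed = child_seed(seed, paste0("mtb", sid)))
      ko[[sid]] <- draw_ko(fct, config, seed = child_seed(seed, paste0("ko", sid)))
    }
  }

  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  count_mat <- do.call(rbind, counts)
  attr(count_mat, "level") <- "genus"
  out <- list(metadata = metadata,
              counts = count_mat,
              metabolites = do.call(rbind, mtb),
              ko = do.call(rbind, ko),
              truth_fct = unlist(truth),
              truth_params = config,
              seed = as.integer(seed))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples from %d infants; %d genera, %d metabolites, %d KOs (seed %d)\n",
    nrow(x$metadata), length(unique(x$metadata$infant_id)),
    ncol(x$counts), ncol(x$metabolites), ncol(x$ko), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `metadata.tsv`, `counts.tsv`, `metabolites.tsv`, `ko.tsv`, a
#' `truth_fct.tsv` label table and a flat key-value `config.txt` (including
#' the seed), in the formats consumed by the reader functions.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_matrix_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write_matrix_tsv(cohort$ko, file.path(dir, "ko.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$truth_fct), fct = cohort$truth_fct),
    file.path(dir, "truth_fct.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- cohort$truth_params
  scalars <- c(n_infants = cfg$n_infants, arm_ratio = cfg$arm_ratio,
               stratum_cutoff = cfg$stratum_cutoff, n_fct = cfg$n_fct,
               treatment_hazard_ratio = cfg$treatment_hazard_ratio,
               depth_mean = cfg$depth_mean, depth_size = cfg$depth_size,
               dropout_prob = cfg$dropout_prob, seed = cohort$seed)
  writeLines(sprintf("%s = %s", names(scalars), scalars),
             file.path(dir, "config.txt"))
  invisible(dir)
}
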