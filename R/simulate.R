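#' Simulate a mixed-type herd survey with planted cluster structure
#'
#' Quantitative variables are Normal around cluster-specific means (cluster
#' means scaled by `separation`, within-cluster noise `noise`); qualitative
#' variables are categorical with a cluster-preferred level whose
#' probability is tilted from uniform by `separation` (tilt
#' `separation / (1 + separation)`). Qualitative types cycle through
#' 3-level nominal, 4-level nominal, 3-level ordinal, symmetric binary and
#' asymmetric binary (coded 0/1). With `plant_removable = TRUE` the survey
#' additionally carries 3 removable quantitative columns (one constant, two
#' exact duplicates) and 8 removable qualitative columns (4 single-level, 4
#' with a dominant level covering all herds but one), emulating a raw
#' instrument that variable editing reduces to the analysis set. The
#' dominant-level plants exceed the default 0.95 editing threshold only with
#' at least 20 herds.
#'
#' The defaults mirror a 30-herd survey in 4 clusters of sizes 13/5/1/11
#' with 23 quantitative + 83 qualitative analysis variables (117 raw
#' columns).
#'
#' @param n_clusters number of planted herd clusters.
#' @param herds_per_cluster integer vector of cluster sizes.
#' @param n_quantitative,n_qualitative analysis variable counts.
#' @param separation nonnegative between-cluster signal scale (0 = no
#'   structure).
#' @param noise within-cluster standard deviation of quantitative variables.
#' @param plant_removable plant the 11 removable columns described above.
#' @param seed RNG seed.
#' @return list with `survey` (a [typed_survey()]), `labels` (named integer
#'   true clusters), `removable` (names of planted removable columns).
#' @export
simulate_survey <- function(n_clusters = 4,
                            herds_per_cluster = c(13, 5, 1, 11),
                            n_quantitative = 23, n_qualitative = 83,
                            separation = 2, noise = 1,
                            plant_removable = TRUE, seed = NULL) {
  stopifnot(n_clusters >= 1, length(herds_per_cluster) == n_clusters,
            all(herds_per_cluster >= 1), separation >= 0, noise > 0,
            n_quantitative >= 1, n_qualitative >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(herds_per_cluster)
  labels <- rep(seq_len(n_clusters), herds_per_cluster)
  herd_ids <- sprintf("herd%02d", seq_len(n))
  names(labels) <- herd_ids
  vals <- list()
  specs <- list()
  add_spec <- function(name, vtype, levels = NA_character_) {
    specs[[length(specs) + 1]] <<- data.frame(
      name = name, vtype = vtype, levels = levels, weight = 1,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_quantitative)) {
    mu <- separation * stats::rnorm(n_clusters)
    nm <- sprintf("quant%02d", j)
    vals[[nm]] <- stats::rnorm(n, mean = mu[labels], sd = noise)
    add_spec(nm, "quantitative")
  }
  tilt <- separation / (1 + separation)
  qual_types <- c("nominal3", "nominal4", "ordinal3", "binsym", "binasym")
  for (j in seq_len(n_qualitative)) {
    type <- qual_types[(j - 1) %% length(qual_types) + 1]
    nm <- sprintf("qual%02d", j)
    lev <- switch(type,
                  nominal3 = c("a", "b", "c"),
                  nominal4 = c("a", "b", "c", "d"),
                  ordinal3 = c("low", "mid", "high"),
                  binsym = c("no", "yes"),
                  binasym = c("0", "1"))
    L <- length(lev)
    pref <- sample.int(L, n_clusters, replace = TRUE)
    p_pref <- 1 / L + tilt * (1 - 1 / L)
    v <- character(n)
    for (i in seq_len(n)) {
      p <- rep((1 - p_pref) / (L - 1), L)
      p[pref[labels[i]]] <- p_pref
      v[i] <- sample(lev, 1, prob = p)
    }
    if (type == "binasym") {
      vals[[nm]] <- as.numeric(v)
      add_spec(nm, "binary_asymmetric")
    } else {
      vals[[nm]] <- v
      add_spec(nm, switch(type,
                          nominal3 = "nominal", nominal4 = "nominal",
                          ordinal3 = "ordinal", binsym = "binary_symmetric"),
               levels = if (type == "ordinal3")
                 paste(lev, collapse = "|") else NA_character_)
    }
  }
  removable <- character(0)
  if (plant_removable) {
    vals[["quant_const"]] <- rep(5, n)
    add_spec("quant_const", "quantitative")
    vals[["quant_dup1"]] <- vals[["quant01"]]
    add_spec("quant_dup1", "quantitative")
    vals[["quant_dup2"]] <- vals[["quant02"]]
    add_spec("quant_dup2", "quantitative")
    for (j in 1:4) {
      nm <- sprintf("qual_const%d", j)
      vals[[nm]] <- rep("only", n)
      add_spec(nm, "nominal")
    }
    for (j in 1:4) {
      nm <- sprintf("qual_dom%d", j)
      v <- rep("common", n)
      v[sample.int(n, 1)] <- "rare"
      vals[[nm]] <- v
      add_spec(nm, "nominal")
    }
    removable <- c("quant_const", "quant_dup1", "quant_dup2",
                   paste0("qual_const", 1:4), paste0("qual_dom", 1:4))
  }
  df <- as.data.frame(vals, stringsAsFactors = FALSE)
  rownames(df) <- herd_ids
  list(survey = typed_survey(df, do.call(rbind, specs), herd_ids),
       labels = labels, removable = removable)
}

#' Simulate a pedigree with true breeding values
#'
#' Founder breeding values are Normal(0, sigma2_a); offspring take the
#' parent average plus Mendelian sampling (variance sigma2_a / 2 with both
#' parents known, 3/4 sigma2_a with only the sire known).
#'
#' @param n_sires,n_dams founder counts (`n_dams = 0` leaves dams unknown).
#' @param n_cows number of recorded-generation females.
#' @param sigma2_a additive genetic variance.
#' @param seed RNG seed.
#' @return list with `pedigree` (a [pedigree_table()]), `bv` (named true
#'   breeding values), `cows` (ids of the recorded generation).
#' @export
simulate_pedigree <- function(n_sires = 20, n_dams = 0, n_cows = 200,
                              sigma2_a = 1, seed = NULL) {
  stopifnot(n_sires >= 1, n_cows >= 1, sigma2_a >= 0)
  if (!is.null(seed)) set.seed(seed)
  sires <- sprintf("S%03d", seq_len(n_sires))
  dams <- if (n_dams > 0) sprintf("D%04d", seq_len(n_dams)) else character(0)
  cows <- sprintf("C%05d", seq_len(n_cows))
  bv <- stats::setNames(stats::rnorm(n_sires + n_dams, 0, sqrt(sigma2_a)),
                        c(sires, dams))
  cs <- sample(sires, n_cows, replace = TRUE)
  cd <- if (n_dams > 0) sample(dams, n_cows, replace = TRUE)
        else rep(NA_character_, n_cows)
  ms_var <- if (n_dams > 0) sigma2_a / 2 else 0.75 * sigma2_a
  pa <- 0.5 * bv[cs] + ifelse(is.na(cd), 0, 0.5 * bv[cd])
  bv_c <- stats::setNames(pa + stats::rnorm(n_cows, 0, sqrt(ms_var)), cows)
  ped <- pedigree_table(c(sires, dams, cows),
                        c(rep(NA, n_sires + n_dams), cs),
                        c(rep(NA, n_sires + n_dams), cd))
  list(pedigree = ped, bv = c(bv, bv_c), cows = cows)
}

#' Simulate test-day records with known variance components
#'
#' Inverts the repeatability test-day model: each cow calves on a random
#' date, is tested on her herd's monthly recording dates (the 15th), and a
#' record is
#' y = mu + breed + lactation + cluster-level test-date environment +
#'     herd-level shift + Legendre lactation curve (DIM) + BV + PE + e.
#' The cluster-shared test-date environment is the explicit mechanism that
#' makes herd-cluster contemporary groups informative when single herds are
#' sparsely occupied.
#'
#' @param ped_sim result of [simulate_pedigree()] (cows get records).
#' @param partition a [herd_partition()] of herd ids to clusters; cows are
#'   assigned to herds uniformly at random.
#' @param records_per_cow monthly test-day records per cow.
#' @param sigma2_pe,sigma2_e permanent-environment and residual variances.
#' @param mu overall mean (kg milk).
#' @param cluster_env_sd SD of the cluster x test-date environmental effect.
#' @param herd_env_sd SD of the constant herd-level shift within cluster.
#' @param breed_effect additive shift for the second breed (breeds are
#'   assigned per herd, roughly half the herds each).
#' @param lact_effects fixed effects of lactations 1..3.
#' @param legendre_coef coefficients of P0..P3 for the DIM curve.
#' @param calving_window date range of calvings.
#' @param dim_window admissible DIM range.
#' @param seed RNG seed.
#' @return list with `records` (data.frame: animal, herd, test_date,
#'   calving_date, dim, lactation, breed, calving_age, Mkg, SCC) and `truth`
#'   (bv, pe, cluster_env table, herd_env, vc).
#' @export
simulate_test_days <- function(ped_sim, partition, records_per_cow = 5,
                               sigma2_pe = 2, sigma2_e = 5, mu = 20,
                               cluster_env_sd = 1.5, herd_env_sd = 0.3,
                               breed_effect = 2,
                               lact_effects = c(0, 2, 3),
                               legendre_coef = c(0, -1.5, 0.6, -0.2),
                               calving_window = as.Date(c("2017-01-01",
                                                          "2017-12-31")),
                               dim_window = c(5, 365), seed = NULL) {
  stopifnot(sigma2_pe >= 0, sigma2_e >= 0, records_per_cow >= 1)
  if (!is.null(seed)) set.seed(seed)
  cows <- ped_sim$cows
  n_cows <- length(cows)
  herds <- partition$herd_ids
  herd_of <- sample(herds, n_cows, replace = TRUE)
  cluster_of_herd <- partition$labels
  breed_of_herd <- stats::setNames(
    rep(c("DSN", "HF"), length.out = length(herds)), herds)
  herd_env <- stats::setNames(stats::rnorm(length(herds), 0, herd_env_sd),
                              herds)
  calving <- sample(seq(calving_window[1], calving_window[2], by = "day"),
                    n_cows, replace = TRUE)
  lact <- sample(1:3, n_cows, replace = TRUE)
  pe <- stats::setNames(stats::rnorm(n_cows, 0, sqrt(sigma2_pe)), cows)
  rows <- vector("list", n_cows)
  for (i in seq_len(n_cows)) {
    # monthly recording dates: 15th of each month after calving + 5 d
    first <- as.Date(format(calving[i] + 20, "%Y-%m-15"))
    if (first < calving[i] + dim_window[1]) first <- seq(first, by = "month",
                                                         length.out = 2)[2]
    tdates <- seq(first, by = "month", length.out = records_per_cow)
    dim <- as.numeric(tdates - calving[i])
    ok <- dim >= dim_window[1] & dim <= dim_window[2]
    rows[[i]] <- data.frame(animal = cows[i], herd = herd_of[i],
                            test_date = tdates[ok],
                            calving_date = calving[i],
                            dim = dim[ok], lactation = lact[i],
                            breed = unname(breed_of_herd[herd_of[i]]),
                            calving_age = 24 + 12 * (lact[i] - 1) +
                              stats::rnorm(1, 0, 1),
                            stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  # cluster x test-date environment, shared by all herds of a cluster
  key <- paste(cluster_of_herd[rec$herd], rec$test_date, sep = ":")
  env_levels <- unique(key)
  cluster_env <- stats::setNames(
    stats::rnorm(length(env_levels), 0, cluster_env_sd), env_levels)
  P <- legendre_dim(rec$dim, order = 3, window = dim_window)
  curve <- drop(P %*% legendre_coef)
  y <- mu +
    ifelse(rec$breed == "HF", breed_effect, 0) +
    lact_effects[rec$lactation] +
    cluster_env[key] + herd_env[rec$herd] + curve +
    ped_sim$bv[rec$animal] + pe[rec$animal] +
    stats::rnorm(nrow(rec), 0, sqrt(sigma2_e))
  rec$Mkg <- as.numeric(y)
  rec$SCC <- stats::rlnorm(nrow(rec), meanlog = log(1e5), sdlog = 0.9)
  list(records = rec,
       truth = list(bv = ped_sim$bv, pe = pe,
                    cluster_env = cluster_env, herd_env = herd_env,
                    herd_of = stats::setNames(herd_of, cows),
                    sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
                    mu = mu))
}

#' Simulate fertility records (CFI and SFI)
#'
#' CFI (days from calving to first insemination) is a linear model in
#' breed, insemination month, lactation, herd cluster, semen type and
#' insemination age with iid animal and service-sire random effects; SFI is
#' Bernoulli with the analogous logit-scale linear predictor. Each cow
#' contributes one record per lactation, with one to three lactations
#' (probabilities 0.7/0.2/0.1, so ~1.4 records per cow), which keeps the
#' animal variance identifiable.
#'
#' @param partition a [herd_partition()].
#' @param n_cows number of cows.
#' @param cfi_cluster_effects,sfi_cluster_effects per-cluster fixed shifts
#'   (days; logits). Recycled to the number of clusters.
#' @param mu_cfi baseline CFI (days).
#' @param mu_sfi baseline SFI logit.
#' @param sigma_animal,sigma_sire,sigma_e random-effect and residual SDs
#'   (CFI scale; the random effects also enter the SFI logit).
#' @param n_service_sires service-sire pool size.
#' @param seed RNG seed.
#' @return list with `records` (animal, herd, breed, lactation,
#'   insem_month, semen, service_sire, insem_age, CFI, SFI) and `truth`.
#' @export
simulate_fertility <- function(partition, n_cows = 500,
                               cfi_cluster_effects = 0,
                               sfi_cluster_effects = 0,
                               mu_cfi = 75, mu_sfi = 0.5,
                               sigma_animal = 5, sigma_sire = 3,
                               sigma_e = 12, n_service_sires = 20,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- partition$k
  cfi_eff <- rep_len(cfi_cluster_effects, k)
  sfi_eff <- rep_len(sfi_cluster_effects, k)
  herds <- partition$herd_ids
  cows <- sprintf("F%05d", seq_len(n_cows))
  herd_of_cow <- stats::setNames(sample(herds, n_cows, replace = TRUE), cows)
  sires <- sprintf("SS%03d", seq_len(n_service_sires))
  u_a <- stats::setNames(stats::rnorm(n_cows, 0, sigma_animal), cows)
  u_s <- stats::setNames(stats::rnorm(n_service_sires, 0, sigma_sire), sires)
  n_lact <- sample(1:3, n_cows, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  animal <- rep(cows, n_lact)
  lact <- unlist(lapply(n_lact, seq_len))
  n <- length(animal)
  herd_of <- unname(herd_of_cow[animal])
  cl <- partition$labels[herd_of]
  srv <- sample(sires, n, replace = TRUE)
  mi <- sample(1:12, n, replace = TRUE)
  semen <- sample(c("fresh", "frozen", "natural"), n, replace = TRUE)
  breed <- stats::setNames(rep(c("DSN", "HF"),
                               length.out = length(herds)), herds)[herd_of]
  age <- 24 + 12 * (lact - 1) + stats::rnorm(n, 0, 1)
  lp_common <- (breed == "HF") * 2 + 0.5 * (lact - 1) +
    (semen == "natural") * 1
  cfi <- mu_cfi + lp_common + cfi_eff[cl] + u_a[animal] + u_s[srv] +
    stats::rnorm(n, 0, sigma_e)
  cfi <- pmax(cfi, 20)
  logit <- mu_sfi + 0.05 * lp_common + sfi_eff[cl] +
    (u_a[animal] + u_s[srv]) / 10
  sfi <- stats::rbinom(n, 1, stats::plogis(logit))
  rec <- data.frame(animal = animal, herd = herd_of,
                    breed = unname(breed),
                    lactation = lact, insem_month = mi, semen = semen,
                    service_sire = srv, insem_age = age,
                    CFI = unname(cfi), SFI = sfi, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(records = rec,
       truth = list(u_animal = u_a, u_sire = u_s,
                    cfi_cluster_effects = cfi_eff,
                    sfi_cluster_effects = sfi_eff))
}
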