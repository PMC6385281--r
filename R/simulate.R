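#' Simulation configuration
#'
#' Builds and validates the configuration of the forward-time segregation
#' simulator.  The model has two interacting components.  (1) A single
#' autosomal susceptibility allele under parent-of-origin genomic
#' imprinting: a carrier parent transmits the allele with probability 1/2;
#' under `imprinting_mode = "maternal"` the maternally transmitted copy is
#' silenced, so the allele is *expressed* only when it came from the father
#' (and conversely under `"paternal"`; `"both"` expresses either copy,
#' `"none"` expresses nothing).  (2) Mother-son microchimerism: carrying a
#' carrier male fetus leaves one persistent unit ("letter") of
#' susceptibility load in the mother.  Letters pass down the maternal line:
#' every child receives the mother's current letter count at birth, so later
#' sibs receive more (the birth-order effect) and load accumulates over
#' generations (anticipation).  Sons express received letters at
#' `strong_unit_weight` each, daughters at `weak_unit_weight`
#' (`daughter_transfer = "equal"` equalizes the weights, merging the strong
#' and weak letter series); a mother's own acquired letters count strongly
#' for herself.  An individual manifests disease when it carries an
#' expressed allele and its weighted load reaches `disease_threshold` units;
#' expressed carriers below the threshold are silent bystanders.
#'
#' @param seed integer RNG seed.
#' @param generations number of generations simulated.
#' @param founder_couples founding couples in generation 1 (in
#'   `"nuclear-families"` mode, the number of families).
#' @param carrier_founders number of founder individuals carrying the
#'   allele.
#' @param founder_letters mean (Poisson) microchimeristic letter count of
#'   generation-1 founder mothers.  The founding couples are a slice of an
#'   old, already loaded population, whereas immigrant wives marrying in
#'   later start unloaded lines.
#' @param mean_sibship mean number of children per couple.
#' @param sibship_dispersion `NA` for Poisson sibship sizes, otherwise the
#'   negative-binomial size parameter.
#' @param sex_ratio probability that a newborn is male.
#' @param imprinting_mode `"maternal"`, `"paternal"`, `"both"` or `"none"`.
#' @param strong_unit_weight,weak_unit_weight expressed load per letter in
#'   sons and daughters.
#' @param letters_cap maximum letters a mother can transmit (the letter
#'   alphabet A-G).
#' @param inducer_prob background probability that a male fetus who does
#'   not carry the specific imprinted allele still induces microchimerism.
#'   Susceptibility is polygenic: beside the one imprinted locus followed
#'   explicitly, sons carry unspecific susceptibility genes from the wider
#'   genomic landscape, and any such son marks his mother.  The imprinted
#'   allele controls the expression pattern; the inducer background keeps
#'   the microchimeristic load a population-wide process.
#' @param disease_threshold weighted load units required for disease.
#' @param penetrance probability that an individual meeting the genetic and
#'   load requirements actually manifests disease; the remainder are silent
#'   bystanders, carriers of the full susceptibility genotype without the
#'   pathognomonic mutation.
#' @param imprint_escape probability that a maternally transmitted
#'   (imprinted) copy nevertheless expresses in a daughter of a deeply
#'   loaded matriline (at least `escape_gate` letters).  Extreme
#'   microchimeristic load perturbs the imprint through the mother-daughter
#'   channel, and susceptibility that breaks through carries the full
#'   (strong) expression of the accumulated letters, so the most heavily
#'   loaded matrilines produce manifest female disease of maternal origin.
#' @param escape_gate letter count from which the mother-daughter
#'   breakthrough can operate.
#' @param paternal_female_attenuation multiplier on the manifestation
#'   probability of a female whose only expressed copy is paternally
#'   transmitted.  Female manifestation is matrilineally potentiated in
#'   this model; paternally derived susceptibility lacks the
#'   mother-daughter microchimeristic reinforcement and rarely completes in
#'   daughters.
#' @param sporadic_rate baseline probability that a non-founder woman
#'   develops sporadic (non-familial) disease irrespective of the followed
#'   susceptibility system; most malignant blood disorders in a population
#'   are sporadic, and they enter the pedigree as pattern-free affected
#'   relatives in both parental lines.
#' @param sporadic_male_bias multiplicative male excess of the sporadic
#'   rate (registry-like male predominance).  Under
#'   `daughter_transfer = "equal"` the merged expression series applies to
#'   the background too and the bias is dropped.
#' @param sporadic_slope dose-response of the sporadic background on the
#'   raw letter count; may be steeper than the followed system's slope
#'   because the background aggregates many load-potentiated systems.
#' @param penetrance_slope dose-response of manifestation on the
#'   microchimeristic letter count (anticipation as increasing severity
#'   with accumulated load): the manifestation probability is
#'   `penetrance * ((1 - slope) + slope * letters / letters_cap)`.
#'   `0` gives uniform, load-independent ("diluted") expression in which
#'   the strong/weak letter distinctions carry no extra weight.
#' @param daughter_transfer `"weak"` or `"equal"`.
#' @param inbreeding_mode `"one-pedigree"` (one connected multi-generation
#'   family with within-pedigree matings) or `"nuclear-families"` (many
#'   small independent families with unrelated parents).
#' @param within_mating fraction of each generation marrying inside the
#'   pedigree (one-pedigree mode).
#' @param marry_in_male,marry_in_female probability that a pedigree member
#'   of that sex left over by the within-pedigree marriage market marries an
#'   immigrant founder.  The asymmetric defaults emulate the island
#'   cohort's female-biased marriage immigration (seafaring men bringing
#'   wives home): immigrant wives have no pedigree kin, so their children
#'   have no visible matrilineal relatives and start a fresh
#'   microchimeristic line.
#' @param max_couples carrying capacity: couples per generation.
#' @param immigrant_carrier_prob probability that a marrying-in founder
#'   carries the allele.
#' @param loss_prob per-letter probability of loss at transmission (the
#'   model's susceptibility-depletion route; off by default).
#' @param onset_base,anticipation_slope,onset_min,onset_sd onset age model:
#'   `onset_base - anticipation_slope * load` plus Gaussian noise, floored.
#' @param birth_year_base calendar year of the founder generation.
#' @param diagnosis_probs named probability vector (ICD-10 codes) used to
#'   assign a diagnosis to affected individuals; default is the island
#'   cohort's LPD mix.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       generations = 6L,
                       founder_couples = 12L,
                       carrier_founders = 4L,
                       founder_letters = 3,
                       mean_sibship = 4.2,
                       sibship_dispersion = NA_real_,
                       sex_ratio = 0.5,
                       imprinting_mode = c("maternal", "paternal", "both", "none"),
                       strong_unit_weight = 1.0,
                       weak_unit_weight = 0.5,
                       letters_cap = 7L,
                       inducer_prob = 1.0,
                       disease_threshold = 2,
                       penetrance = 0.35,
                       imprint_escape = 1.0,
                       escape_gate = 3L,
                       paternal_female_attenuation = 0.3,
                       sporadic_rate = 0.023,
                       sporadic_male_bias = 1.7,
                       sporadic_slope = 0.9,
                       penetrance_slope = 0.7,
                       daughter_transfer = c("weak", "equal"),
                       inbreeding_mode = c("one-pedigree", "nuclear-families"),
                       within_mating = 0.8,
                       marry_in_male = 0.9,
                       marry_in_female = 0.25,
                       max_couples = 55L,
                       immigrant_carrier_prob = 0.05,
                       loss_prob = 0,
                       onset_base = 75,
                       anticipation_slope = 4,
                       onset_min = 15,
                       onset_sd = 6,
                       birth_year_base = 1860L,
                       diagnosis_probs = NULL) {
  cfg <- list(
    seed = as.integer(seed), generations = as.integer(generations),
    founder_couples = as.integer(founder_couples),
    carrier_founders = as.integer(carrier_founders),
    founder_letters = founder_letters,
    mean_sibship = mean_sibship, sibship_dispersion = sibship_dispersion,
    sex_ratio = sex_ratio,
    imprinting_mode = match.arg(imprinting_mode),
    strong_unit_weight = strong_unit_weight,
    weak_unit_weight = weak_unit_weight,
    letters_cap = as.integer(letters_cap),
    inducer_prob = inducer_prob,
    disease_threshold = disease_threshold,
    penetrance = penetrance,
    imprint_escape = imprint_escape,
    escape_gate = as.integer(escape_gate),
    paternal_female_attenuation = paternal_female_attenuation,
    sporadic_rate = sporadic_rate,
    sporadic_male_bias = sporadic_male_bias,
    sporadic_slope = sporadic_slope,
    penetrance_slope = penetrance_slope,
    daughter_transfer = match.arg(daughter_transfer),
    inbreeding_mode = match.arg(inbreeding_mode),
    within_mating = within_mating,
    marry_in_male = marry_in_male, marry_in_female = marry_in_female,
    max_couples = as.integer(max_couples),
    immigrant_carrier_prob = immigrant_carrier_prob,
    loss_prob = loss_prob,
    onset_base = onset_base, anticipation_slope = anticipation_slope,
    onset_min = onset_min, onset_sd = onset_sd,
    birth_year_base = as.integer(birth_year_base),
    diagnosis_probs = diagnosis_probs %||% default_diagnosis_probs()
  )
  if (cfg$daughter_transfer == "equal") cfg$weak_unit_weight <- cfg$strong_unit_weight
  probs <- c(cfg$sex_ratio, cfg$within_mating, cfg$immigrant_carrier_prob,
             cfg$loss_prob, cfg$marry_in_male, cfg$marry_in_female,
             cfg$inducer_prob, cfg$penetrance, cfg$penetrance_slope,
             cfg$imprint_escape, cfg$sporadic_rate)
  if (any(probs < 0 | probs > 1)) {
    mbd_error("mbdfam_config", "probabilities must be in [0, 1]")
  }
  if (cfg$generations < 2L) mbd_error("mbdfam_config", "generations must be >= 2")
  if (cfg$disease_threshold < 1) mbd_error("mbdfam_config", "disease_threshold must be >= 1")
  if (cfg$carrier_founders > 2L * cfg$founder_couples) {
    mbd_error("mbdfam_config", "more carrier founders than founders")
  }
  if (abs(sum(cfg$diagnosis_probs) - 1) > 1e-8 || any(cfg$diagnosis_probs < 0)) {
    mbd_error("mbdfam_config", "diagnosis_probs must be a probability vector")
  }
  class(cfg) <- "sim_config"
  cfg
}

# island-cohort LPD diagnosis mix, used for pleiotropic diagnosis assignment
default_diagnosis_probs <- function() {
  cc <- cohort_counts()
  lpd <- cc[cc$group == "LPD" & cc$faroe_n > 0, , drop = FALSE]
  setNames(lpd$faroe_n / sum(lpd$faroe_n), lpd$icd10)
}

#' Transmit the imprinted susceptibility allele to a child
#'
#' A carrier parent transmits with probability 1/2; whether a transmitted
#' copy is expressed depends on the imprinting mode and the parent's sex
#' (maternal imprinting silences the maternal copy, so only paternally
#' transmitted alleles express).
#'
#' @param parent_carrier logical, is the parent a carrier.
#' @param parent_sex `"male"` or `"female"`.
#' @param mode imprinting mode.
#' @return list with `inherited` (logical) and `expressed` (logical: the
#'   transmitted copy is an expressed copy).
#' @export
transmit_allele <- function(parent_carrier, parent_sex,
                            mode = c("maternal", "paternal", "both", "none")) {
  mode <- match.arg(mode)
  inherited <- isTRUE(parent_carrier) && runif(1) < 0.5
  expressed <- inherited && switch(mode,
    maternal = parent_sex == "male",
    paternal = parent_sex == "female",
    both = TRUE,
    none = FALSE)
  list(inherited = inherited, expressed = expressed)
}

#' New microchimerism state for a mother
#' @param inherited_letters letters the mother herself received at birth.
#' @return list used by [update_microchimerism()].
#' @export
mother_state <- function(inherited_letters = 0L) {
  list(inherited = as.integer(inherited_letters), acquired = 0L,
       next_birth = 1L)
}

#' Update the mother-son microchimerism load at a birth
#'
#' Births must be processed in birth order.  The child receives the mother's
#' current letter count (inherited plus acquired so far, capped); a carrier
#' male fetus then adds one acquired letter to the mother.
#'
#' @param mother a [mother_state()].
#' @param fetus_carrier logical.
#' @param fetus_sex `"male"` or `"female"`.
#' @param birth_index 1-based position of this birth.
#' @param letters_cap cap on transmissible letters.
#' @return list with `mother` (updated state) and `child_letters`.
#' @export
update_microchimerism <- function(mother, fetus_carrier, fetus_sex,
                                  birth_index, letters_cap = 7L) {
  if (birth_index != mother$next_birth) {
    mbd_error("mbdfam_birth_order",
              sprintf("birth %d processed out of order (expected %d)",
                      birth_index, mother$next_birth))
  }
  child_letters <- min(letters_cap, mother$inherited + mother$acquired)
  if (isTRUE(fetus_carrier) && fetus_sex == "male") {
    mother$acquired <- mother$acquired + 1L
  }
  mother$next_birth <- mother$next_birth + 1L
  list(mother = mother, child_letters = as.integer(child_letters))
}

#' Manifestation rule
#'
#' An individual manifests disease when it has an expressed susceptibility
#' allele and a weighted microchimeristic load of at least the disease
#' threshold; onset age decreases linearly with load (anticipation).
#'
#' @param expressed logical.
#' @param units weighted load units.
#' @param theta disease threshold in units.
#' @param onset_base,slope,onset_min onset-age model parameters.
#' @return list with `affected` and `onset_age` (`NA` if unaffected).
#' @export
manifest <- function(expressed, units, theta = 2, onset_base = 75,
                     slope = 4, onset_min = 15) {
  affected <- isTRUE(expressed) && units >= theta
  onset <- if (affected) max(onset_min, onset_base - slope * units) else NA_real_
  list(affected = affected, onset_age = onset)
}
#' Run the forward-time segregation simulator
#'
#' Simulates a pedigree under the imprinting plus mother-son microchimerism
#' model of [sim_config()], returning the pedigree, a phenotype table and
#' the per-individual ground truth.  Reproducible: a fixed seed yields
#' identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result` with elements `ped` (a `pedigree`),
#'   `phenotype` (data frame `iid`, `icd10`, `birth_year`, `onset_year`),
#'   `truth` (per-individual carrier/expression/load/affection state) and
#'   `config`.  If the model produces no affected individual the result
#'   carries attribute `extinct = TRUE` (reported, not an error).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  nuclear <- cfg$inbreeding_mode == "nuclear-families"

  # population state, one slot per individual
  nf <- cfg$founder_couples
  n <- 2L * nf
  st <- list(
    family = if (nuclear) rep(sprintf("F%03d", seq_len(nf)), each = 2L)
             else rep("F1", n),
    father = rep(NA_character_, n), mother = rep(NA_character_, n),
    sex = rep(c("male", "female"), nf),
    gen = rep(1L, n),
    by = as.integer(rep(cfg$birth_year_base + sample.int(12L, nf, TRUE) - 1L,
                        each = 2L) + rep(c(0L, 1L), nf)),
    ap = rep(FALSE, n), am = rep(FALSE, n),
    letters = integer(n), acquired = integer(n)
  )
  carriers <- sample.int(n, min(cfg$carrier_founders, n))
  from_father <- runif(length(carriers)) < 0.5
  st$ap[carriers[from_father]] <- TRUE
  st$am[carriers[!from_father]] <- TRUE
  fem <- st$sex == "female"
  st$letters[fem] <- pmin(cfg$letters_cap, rpois(sum(fem), cfg$founder_letters))
  couples <- cbind(seq.int(1L, n, 2L), seq.int(2L, n, 2L))

  for (g in seq_len(cfg$generations - 1L)) {
    nc <- nrow(couples)
    if (!nc) break
    nk <- if (is.na(cfg$sibship_dispersion)) rpois(nc, cfg$mean_sibship)
          else rnbinom(nc, size = cfg$sibship_dispersion, mu = cfg$mean_sibship)
    ci <- rep(seq_len(nc), nk)
    B <- length(ci)
    if (!B) break
    bidx <- sequence(nk)
    fidx <- couples[ci, 1L]; midx <- couples[ci, 2L]
    csex <- ifelse(runif(B) < cfg$sex_ratio, "male", "female")
    c_ap <- (st$ap[fidx] | st$am[fidx]) & runif(B) < 0.5
    c_am <- (st$ap[midx] | st$am[midx]) & runif(B) < 0.5
    inducer <- c_ap | c_am | runif(B) < cfg$inducer_prob
    marks <- inducer & csex == "male"
    # letters received = mother's pre-birth count (inherited + acquired so
    # far); a carrier/inducer male fetus then adds one acquired letter
    fac <- factor(ci, levels = seq_len(nc))
    pre <- unlist(lapply(split(marks, fac), function(v)
      c(0L, cumsum(v))[seq_along(v)]), use.names = FALSE)
    letters <- pmin(cfg$letters_cap, st$letters[midx] + pre)
    if (cfg$loss_prob > 0) {
      pos <- letters > 0L
      letters[pos] <- rbinom(sum(pos), letters[pos], 1 - cfg$loss_prob)
    }
    st$acquired[couples[, 2L]] <- st$acquired[couples[, 2L]] +
      as.integer(vapply(split(marks, fac), sum, 0L))
    cby <- as.integer(round(st$by[midx] + 21 + 2.4 * (bidx - 1L))) +
      sample.int(3L, B, TRUE) - 1L
    off <- length(st$family) + seq_len(B)
    st <- grow_state(st, list(
      family = st$family[fidx],
      father = sprintf("I%05d", fidx), mother = sprintf("I%05d", midx),
      sex = csex, gen = rep(g + 1L, B), by = cby,
      ap = c_ap, am = c_am, letters = as.integer(letters),
      acquired = integer(B)
    ))
    if (g + 1L >= cfg$generations) break
    mk <- .sim_pair(st, off, cfg, gen = g + 1L, nuclear = nuclear)
    st <- mk$st
    couples <- mk$couples
  }
  .sim_finish(st, cfg)
}

grow_state <- function(st, m) {
  for (k in names(m)) st[[k]] <- c(st[[k]], m[[k]])
  st
}

# marriage market for one generation; returns couples (male idx, female idx)
.sim_pair <- function(st, offspring, cfg, gen, nuclear) {
  sex <- st$sex[offspring]
  males <- offspring[sex == "male"]
  females <- offspring[sex == "female"]
  males <- males[sample.int(length(males))]
  females <- females[sample.int(length(females))]

  add_immigrants <- function(st, partners) {
    np <- length(partners)
    if (!np) return(list(st = st, idx = integer()))
    sp_sex <- ifelse(st$sex[partners] == "male", "female", "male")
    carrier <- runif(np) < cfg$immigrant_carrier_prob
    from_father <- runif(np) < 0.5
    idx <- length(st$family) + seq_len(np)
    st <- grow_state(st, list(
      family = st$family[partners],
      father = rep(NA_character_, np), mother = rep(NA_character_, np),
      sex = sp_sex, gen = rep(gen, np),
      by = st$by[partners] + sample.int(5L, np, TRUE) - 3L,
      ap = carrier & from_father, am = carrier & !from_father,
      letters = integer(np), acquired = integer(np)
    ))
    list(st = st, idx = idx)
  }

  if (nuclear) {
    partners <- c(males, females)
    im <- add_immigrants(st, partners)
    st <- im$st
    is_m <- st$sex[partners] == "male"
    couples <- cbind(ifelse(is_m, partners, im$idx),
                     ifelse(is_m, im$idx, partners))
    keep <- seq_len(min(nrow(couples), cfg$max_couples))
    return(list(st = st, couples = couples[keep, , drop = FALSE]))
  }

  # within-pedigree pairs, dropping candidates that would share a parent
  n_within <- floor(cfg$within_mating * min(length(males), length(females)))
  wm <- males[seq_len(n_within)]
  wf <- females[seq_len(n_within)]
  share <- (!is.na(st$father[wm]) & !is.na(st$father[wf]) &
              st$father[wm] == st$father[wf]) |
           (!is.na(st$mother[wm]) & !is.na(st$mother[wf]) &
              st$mother[wm] == st$mother[wf])
  couples <- cbind(wm[!share], wf[!share])
  # everyone else may marry an immigrant founder, at the sex-biased rates
  rest_m <- c(if (n_within < length(males)) males[-seq_len(n_within)], wm[share])
  rest_f <- c(if (n_within < length(females)) females[-seq_len(n_within)], wf[share])
  rest_m <- rest_m[runif(length(rest_m)) < cfg$marry_in_male]
  rest_f <- rest_f[runif(length(rest_f)) < cfg$marry_in_female]
  partners <- c(rest_m, rest_f)
  im <- add_immigrants(st, partners)
  st <- im$st
  if (length(partners)) {
    is_m <- st$sex[partners] == "male"
    couples <- rbind(couples,
                     cbind(ifelse(is_m, partners, im$idx),
                           ifelse(is_m, im$idx, partners)))
  }
  if (nrow(couples) > cfg$max_couples) {
    couples <- couples[sort(sample.int(nrow(couples), cfg$max_couples)), ,
                       drop = FALSE]
  }
  list(st = st, couples = couples)
}

# assemble pedigree/phenotype/truth from the population state
.sim_finish <- function(st, cfg) {
  n <- length(st$family)
  df <- data.frame(
    id = sprintf("I%05d", seq_len(n)),
    family = st$family, father = st$father, mother = st$mother,
    sex = st$sex, gen = st$gen, birth_year = st$by,
    allele_pat = st$ap, allele_mat = st$am,
    letters = st$letters, acquired = st$acquired,
    stringsAsFactors = FALSE
  )
  df$carrier <- df$allele_pat | df$allele_mat
  # Under concomitant ("both") imprinting the maternally transmitted copy
  # expresses through the mother-offspring microchimeristic channel, which
  # is strong toward sons; daughters use it only when the gender barrier is
  # dissolved (daughter_transfer = "equal", the merged strong/weak series).
  mat_route <- df$sex == "male" | cfg$daughter_transfer == "equal"
  # imprint escape: extreme matrilineal load perturbs the imprint in
  # daughters (mother-daughter channel) and lets maternal copies express
  esc <- df$sex == "female" & df$letters >= cfg$escape_gate &
    runif(nrow(df)) < cfg$imprint_escape
  df$expressed <- switch(cfg$imprinting_mode,
    maternal = df$allele_pat | (df$allele_mat & esc),
    paternal = df$allele_mat,
    both = df$allele_pat | (df$allele_mat & (mat_route | esc)),
    none = rep(FALSE, nrow(df)))
  # manifestation depends on the letters received at birth, expressed at the
  # sex-specific weight; a mother's acquired letters feed her transmissions
  # but not her own phenotype
  w_recv <- ifelse(df$sex == "male", cfg$strong_unit_weight, cfg$weak_unit_weight)
  df$units <- df$letters * w_recv
  # susceptibility that broke through the mother-daughter channel carries
  # the strong expression of its letters
  df$units[esc & df$allele_mat] <- df$letters[esc & df$allele_mat] *
    cfg$strong_unit_weight
  # founder letters seed the matrilines they head; the founders' own
  # pre-observation load is unknown and carries no disease risk here
  df$units[df$gen == 1L] <- 0
  eligible <- df$expressed & df$units >= cfg$disease_threshold
  # dose-response on the sex-weighted load: anticipation as severity rising
  # with expressed units (strong letters count fully, weak ones at half)
  dose <- (1 - cfg$penetrance_slope) +
    cfg$penetrance_slope * pmin(df$units, cfg$letters_cap) / cfg$letters_cap
  pen <- cfg$penetrance * dose
  # paternally derived susceptibility is weakly completed in daughters;
  # with equalized transfer the channels are merged and nothing attenuates
  att <- if (cfg$daughter_transfer == "equal") 1 else cfg$paternal_female_attenuation
  pat_only_f <- df$sex == "female" & df$allele_pat & !(df$allele_mat & esc)
  pen[pat_only_f] <- pen[pat_only_f] * att
  bias <- if (cfg$daughter_transfer == "equal") 1 else cfg$sporadic_male_bias
  # the microchimeristic load potentiates every susceptibility system; the
  # background dose follows the raw letter count (mixed systems, both
  # expression strengths)
  dose_bg <- (1 - cfg$sporadic_slope) +
    cfg$sporadic_slope * df$letters / cfg$letters_cap
  spor_p <- cfg$sporadic_rate * ifelse(df$sex == "male", bias, 1) * dose_bg
  if (cfg$imprinting_mode == "none") spor_p <- 0  # fully null generator
  df$sporadic <- df$gen > 1L & runif(nrow(df)) < spor_p
  df$affected <- (eligible & runif(nrow(df)) < pen) | df$sporadic
  onset <- pmax(cfg$onset_min,
                round(cfg$onset_base - cfg$anticipation_slope * df$units +
                        rnorm(nrow(df), 0, cfg$onset_sd)))
  df$onset_age <- ifelse(df$affected, onset, NA_real_)
  df$diagnosis <- NA_character_
  n_aff <- sum(df$affected)
  if (n_aff > 0) {
    df$diagnosis[df$affected] <- sample(names(cfg$diagnosis_probs), n_aff,
                                        replace = TRUE,
                                        prob = cfg$diagnosis_probs)
  }
  ped <- as_pedigree(data.frame(
    family = df$family, id = df$id, father = df$father, mother = df$mother,
    sex = df$sex,
    affected = ifelse(df$affected, "affected", "unaffected"),
    diagnosis = df$diagnosis, birth_year = df$birth_year,
    onset_year = ifelse(df$affected, df$birth_year + df$onset_age, NA_real_),
    stringsAsFactors = FALSE
  ))
  phenotype <- data.frame(iid = df$id, icd10 = df$diagnosis,
                          birth_year = df$birth_year,
                          onset_year = ped$onset_year,
                          stringsAsFactors = FALSE)
  truth <- df[, c("id", "gen", "sex", "carrier", "allele_pat", "allele_mat",
                  "expressed", "letters", "acquired", "units", "sporadic",
                  "affected", "onset_age")]
  allele_from <- ifelse(df$allele_pat & df$allele_mat, "both",
                        ifelse(df$allele_pat, "father",
                               ifelse(df$allele_mat, "mother", "none")))
  truth$allele_from <- allele_from
  out <- list(ped = ped, phenotype = phenotype, truth = truth, config = cfg)
  attr(out, "extinct") <- n_aff == 0L
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("Simulated cohort: %d individuals, %d affected ",
                     "(%s imprinting, %s daughter transfer, theta = %g)\n"),
              nrow(x$ped), sum(x$ped$affected == "affected"),
              x$config$imprinting_mode, x$config$daughter_transfer,
              x$config$disease_threshold))
  if (isTRUE(attr(x, "extinct"))) cat("  note: no affected individual produced\n")
  invisible(x)
}

#' Pooled pattern-recovery cohort
#'
#' Simulates several independent pedigrees under one configuration and
#' pools their affected-relative tables into a single cohort four-group
#' table.  Pooling keeps the per-pedigree lineage sampling noise from
#' dominating the cohort-level pattern, mirroring how a multi-family study
#' accumulates evidence.  Pedigree seeds are derived deterministically from
#' the configuration seed.
#'
#' @param config a [sim_config()]; its `seed` seeds the whole cohort.
#' @param n_pedigrees maximum number of pedigrees to simulate.
#' @param max_probands stop adding pedigrees once this many probands have
#'   accumulated.
#' @param yates passed to [score_four_group()].
#' @return list with `table` (a scored `four_group_table`), `pattern`,
#'   `n_probands`, `n_pedigrees`, `affected_mf` (male/female ratio among
#'   affected) and `truths` (list of per-pedigree ground-truth tables).
#' @export
pattern_cohort <- function(config = sim_config(), n_pedigrees = 50L,
                           max_probands = 500L) {
  stopifnot(inherits(config, "sim_config"))
  n_pro <- 0L; n_ped <- 0L; n_m <- 0L; n_f <- 0L
  truths <- list()
  obs_list <- list()
  for (j in seq_len(n_pedigrees)) {
    cfg_j <- config
    cfg_j$seed <- config$seed * 1009L + j
    sim <- simulate_cohort(cfg_j)
    truths[[j]] <- sim$truth
    aff <- sim$ped$affected == "affected"
    if (sum(aff) < 3L) next
    seg <- analyze_segregation(sim$ped)
    obs_list[[length(obs_list) + 1L]] <- seg$table$obs
    n_pro <- n_pro + nrow(seg$records)
    n_ped <- n_ped + 1L
    n_m <- n_m + sum(aff & sim$ped$sex == "male")
    n_f <- n_f + sum(aff & sim$ped$sex == "female")
    if (n_pro >= max_probands) break
  }
  tab <- score_four_group_replicates(obs_list)
  list(table = tab, pattern = tab$pattern, n_probands = n_pro,
       n_pedigrees = n_ped, affected_mf = n_m / max(1L, n_f),
       obs_list = obs_list, truths = truths)
}
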