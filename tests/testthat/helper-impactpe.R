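# shared fixtures, built in code

the <- new.env()

default_registry <- function() {
  if (is.null(the$registry)) the$registry <- load_registry()
  the$registry
}

default_coef <- function() {
  if (is.null(the$coef)) the$coef <- impact_coefficients()
  the$coef
}

small_population <- function(n = 2000, seed = 7, ...) {
  key <- paste0("pop_", n, "_", seed, "_", length(list(...)))
  if (is.null(the[[key]])) {
    the[[key]] <- simulate_population(sim_config(n_members = n, seed = seed, ...),
                                      default_registry(), default_coef())
  }
  the[[key]]
}

# all-false comorbidity profile at a given age
bare_profile <- function(age, set_true = character()) {
  p <- as.data.frame(setNames(as.list(rep(FALSE, 11)), impact_comorbidities()))
  p$age <- age
  for (nm in set_true) p[[nm]] <- TRUE
  p
}

# O(n^2) all-pairs AUC oracle, ties counted one half
auc_brute_force <- function(risks, outcomes) {
  ev <- risks[as.logical(outcomes)]
  ne <- risks[!as.logical(outcomes)]
  tot <- 0
  for (e in ev) tot <- tot + sum(e > ne) + 0.5 * sum(e == ne)
  tot / (length(ev) * length(ne))
}

# one inpatient claims row
claim_row <- function(member_id, dx, proc = "", admit = as.Date("2012-03-01"),
                      discharge = admit + 4, setting = "inpatient",
                      status = "alive", source = "community",
                      claim_id = "C1") {
  data.frame(claim_id = claim_id, member_id = member_id, setting = setting,
             admit_date = admit, discharge_date = discharge,
             diagnosis_codes = dx, procedure_codes = proc,
             discharge_status = status, admission_source = source,
             stringsAsFactors = FALSE)
}
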