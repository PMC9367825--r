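#' Economic constants for the cost-utility analysis
#'
#' Literature-based constants used throughout the cost, cost-utility and
#' cost-threshold calculations: the lifetime medical cost of one HIV
#' infection (T), society's willingness to pay for a quality-adjusted life
#' year (W), the annual HIV transmission rate for a person who is not
#' virally suppressed relative to one who is, the QALYs saved per
#' person-year of viral suppression through improved individual health, the
#' QALYs saved per averted HIV infection, and a conservative
#' cost-effectiveness threshold commonly used in sensitivity statements.
#'
#' @param lifetime_treatment_cost USD, lifetime HIV medical cost averted per
#'   transmission averted (default 382954)
#' @param wtp_per_qaly USD per QALY society is willing to pay
#'   (default 195838.58)
#' @param transmission_rate annual transmission rate per unsuppressed
#'   person-year (default 0.061)
#' @param qaly_per_py_suppressed QALYs saved per person-year of suppression
#'   (default 0.039)
#' @param qaly_per_averted_infection QALYs saved per averted infection
#'   (default 5.83)
#' @param conservative_threshold USD per QALY conservative threshold
#'   (default 1e5)
#' @return a list of class `econ_constants`
#' @export
econ_constants <- function(lifetime_treatment_cost = 382954,
                           wtp_per_qaly = 195838.58,
                           transmission_rate = 0.061,
                           qaly_per_py_suppressed = 0.039,
                           qaly_per_averted_infection = 5.83,
                           conservative_threshold = 1e5) {
  k <- list(
    lifetime_treatment_cost = lifetime_treatment_cost,
    wtp_per_qaly = wtp_per_qaly,
    transmission_rate = transmission_rate,
    qaly_per_py_suppressed = qaly_per_py_suppressed,
    qaly_per_averted_infection = qaly_per_averted_infection,
    conservative_threshold = conservative_threshold
  )
  bad <- names(k)[vapply(k, function(v) !is.numeric(v) || length(v) != 1 || v <= 0, logical(1))]
  if (length(bad)) stop_data("econ constants must be positive scalars: %s", paste(bad, collapse = ", "))
  structure(k, class = "econ_constants")
}

#' Construct a validated per-clinic cost-input record set
#'
#' @param clinic_id character clinic identifiers
#' @param n_clients positive integer clients enrolled per clinic
#' @param n_contacts positive integer client contacts per clinic
#' @param client_costs,staff_costs,materials_costs non-negative USD component
#'   costs (client-borne, staff-related, materials/consumables)
#' @param net_suppressed non-negative integer, net number of participants who
#'   became virally suppressed during the programme (person-years proxy)
#' @return a tibble with one row per clinic
#' @export
cost_inputs <- function(clinic_id, n_clients, n_contacts,
                        client_costs, staff_costs, materials_costs,
                        net_suppressed = NA_integer_) {
  x <- tibble::tibble(
    clinic_id = as.character(clinic_id),
    n_clients = as.integer(n_clients),
    n_contacts = as.integer(n_contacts),
    client_costs = as.numeric(client_costs),
    staff_costs = as.numeric(staff_costs),
    materials_costs = as.numeric(materials_costs),
    net_suppressed = as.integer(net_suppressed)
  )
  if (any(x$n_clients < 1)) stop_data("n_clients must be >= 1")
  for (col in c("client_costs", "staff_costs", "materials_costs")) {
    if (any(x[[col]] < 0)) stop_data("negative cost component in '%s'", col)
  }
  x
}

#' Total programme cost under a costing perspective
#'
#' The societal perspective sums all resources consumed (client-borne, staff,
#' materials); the payor's perspective excludes client-borne costs.
#' Evaluation costs are excluded upstream (never entered as inputs).
#'
#' @param inputs one or more rows of [cost_inputs()]
#' @param perspective `"societal"` or `"payor"`
#' @return USD totals, rounded to the cent, one per row of `inputs`
#' @export
total_cost <- function(inputs, perspective = c("societal", "payor")) {
  perspective <- match.arg(perspective)
  comp <- c("client_costs", "staff_costs", "materials_costs")
  if (any(vapply(comp, function(cl) any(inputs[[cl]] < 0), logical(1))))
    stop_data("negative cost component")
  societal <- inputs$client_costs + inputs$staff_costs + inputs$materials_costs
  round_cents(if (perspective == "societal") societal else societal - inputs$client_costs)
}

#' Unit costs per client and per contact
#'
#' @param total USD total cost
#' @param n_clients,n_contacts positive denominators
#' @return list with `per_client` and `per_contact`, rounded to the cent
#' @export
unit_costs <- function(total, n_clients, n_contacts) {
  if (any(n_clients < 1) || any(n_contacts < 1)) stop_data("unit cost denominator must be >= 1")
  list(per_client = round_cents(total / n_clients),
       per_contact = round_cents(total / n_contacts))
}

#' HIV infections averted
#'
#' Person-years of viral suppression (proxied by the net number of
#' participants who became suppressed) times the annual transmission rate,
#' reported rounded to 2 decimals.
#'
#' @param net_suppressed non-negative person-years of suppression
#' @param constants an [econ_constants()] object
#' @return infections averted, 2 dp
#' @export
infections_averted <- function(net_suppressed, constants = econ_constants()) {
  if (any(net_suppressed < 0)) stop_data("net_suppressed must be non-negative")
  round_half_up(net_suppressed * constants$transmission_rate, 2)
}

#' QALYs saved through improved health (Q1), averted infections (Q2), total (Q)
#'
#' Q1 = 0.039 per person-year of suppression; Q2 = 5.83 per averted
#' infection, where the averted-infection count enters already rounded to 2
#' decimals (the convention the published worked examples use); Q = Q1 + Q2.
#'
#' @param net_suppressed person-years of suppression
#' @param A infections averted, as reported (2 dp)
#' @param constants an [econ_constants()] object
#' @return list with `Q1`, `Q2`, `Q`
#' @export
qalys_saved <- function(net_suppressed, A, constants = econ_constants()) {
  if (any(net_suppressed < 0) || any(A < 0)) stop_data("QALY inputs must be non-negative")
  Q1 <- round_half_up(constants$qaly_per_py_suppressed * net_suppressed, 2)
  Q2 <- round_half_up(constants$qaly_per_averted_infection * A, 2)
  list(Q1 = Q1, Q2 = Q2, Q = Q1 + Q2)
}

#' Cost-utility ratio (net cost per QALY)
#'
#' R = (C - A*T) / (A*Q), evaluated on the 2-dp-reported A and Q. Negative
#' values mean the programme costs less than the treatment costs it averts
#' (dominant, i.e. cost-saving); the magnitude is what cost tables print.
#'
#' @param C USD total programme cost
#' @param A infections averted (2 dp)
#' @param Q total QALYs saved (2 dp)
#' @param constants an [econ_constants()] object
#' @return list with `R_signed`, `R_reported` (magnitude, cents),
#'   `dominant`, `cost_effective` (vs W) and
#'   `cost_effective_conservative` (vs the conservative threshold)
#' @export
cost_utility_ratio <- function(C, A, Q, constants = econ_constants()) {
  if (any(A <= 0) || any(Q <= 0)) stop_data("cost-utility ratio undefined for A = 0 or Q = 0")
  R_signed <- (C - A * constants$lifetime_treatment_cost) / (A * Q)
  R_signed <- round_cents(R_signed)
  R_reported <- abs(R_signed)
  list(
    R_signed = R_signed,
    R_reported = R_reported,
    dominant = R_signed < 0,
    cost_effective = R_reported < constants$wtp_per_qaly,
    cost_effective_conservative = R_reported < constants$conservative_threshold
  )
}

#' Cost-saving and cost-effectiveness thresholds
#'
#' C/T is the number of HIV transmissions that must be averted for the
#' programme to be cost-saving; C/W the number of QALYs that must be saved
#' for it to be cost-effective. A combined form C/(T + Q*W) is also reported;
#' it takes Q = QALYs per averted infection by default since the combined
#' formula is stated per transmission averted.
#'
#' @param C USD total programme cost
#' @param constants an [econ_constants()] object
#' @param Q QALYs used in the combined threshold (default
#'   `constants$qaly_per_averted_infection`)
#' @return list with `cost_saving` (C/T), `cost_effectiveness` (C/W) and
#'   `stated` (C/(T + Q*W)), each rounded to 2 decimals
#' @export
cost_thresholds <- function(C, constants = econ_constants(), Q = NULL) {
  if (any(C < 0)) stop_data("C must be non-negative")
  Q <- Q %||% constants$qaly_per_averted_infection
  list(
    cost_saving = round_half_up(C / constants$lifetime_treatment_cost, 2),
    cost_effectiveness = round_half_up(C / constants$wtp_per_qaly, 2),
    stated = round_half_up(C / (constants$lifetime_treatment_cost + Q * constants$wtp_per_qaly), 2)
  )
}

#' Full per-clinic cost, cost-utility and threshold analysis
#'
#' Runs the complete chain for each clinic: perspective totals, unit costs,
#' infections averted, QALYs saved, the cost-utility ratio and the threshold
#' quantities.
#'
#' @param inputs a [cost_inputs()] tibble with `net_suppressed` filled in
#' @param constants an [econ_constants()] object
#' @return a tibble, one row per clinic, with all reported quantities
#' @export
cost_utility_analysis <- function(inputs, constants = econ_constants()) {
  if (any(is.na(inputs$net_suppressed)))
    stop_data("net_suppressed is required for the cost-utility analysis")
  C_soc <- total_cost(inputs, "societal")
  C_pay <- total_cost(inputs, "payor")
  uc_soc <- unit_costs(C_soc, inputs$n_clients, inputs$n_contacts)
  uc_pay <- unit_costs(C_pay, inputs$n_clients, inputs$n_contacts)
  A <- infections_averted(inputs$net_suppressed, constants)
  Q <- qalys_saved(inputs$net_suppressed, A, constants)
  R <- cost_utility_ratio(C_soc, A, Q$Q, constants)
  th <- cost_thresholds(C_soc, constants)
  tibble::tibble(
    clinic_id = inputs$clinic_id,
    C_societal = C_soc,
    C_payor = C_pay,
    per_client_societal = uc_soc$per_client,
    per_contact_societal = uc_soc$per_contact,
    per_client_payor = uc_pay$per_client,
    per_contact_payor = uc_pay$per_contact,
    net_suppressed = inputs$net_suppressed,
    infections_averted = A,
    Q1 = Q$Q1,
    Q2 = Q$Q2,
    Q_total = Q$Q,
    R_signed = R$R_signed,
    R_reported = R$R_reported,
    dominant = R$dominant,
    cost_effective = R$cost_effective,
    cost_effective_conservative = R$cost_effective_conservative,
    threshold_cost_saving = th$cost_saving,
    threshold_cost_effectiveness = th$cost_effectiveness,
    threshold_stated = th$stated
  )
}

#' Published per-clinic cost inputs
#'
#' The three-clinic cost-input table of the worked example this package's
#' economic chain is checked against: enrolment counts, contact counts,
#' component costs and the net number of participants who became virally
#' suppressed. Contact counts are implied by the printed per-contact unit
#' costs (they are not printed themselves). The materials/consumables
#' components of clinics B and C are back-derived from their printed
#' societal totals: C's component cell is not printed at all, and B's
#' printed components under-sum the printed total, which the printed payor
#' total (societal minus client costs) confirms as authoritative. Values
#' are read from `inst/extdata/cost_inputs_published.csv`.
#'
#' @return a [cost_inputs()] tibble with three clinics
#' @export
published_cost_inputs <- function() {
  path <- system.file("extdata", "cost_inputs_published.csv", package = "cascadecea", mustWork = TRUE)
  read_cost_inputs(path)
}
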