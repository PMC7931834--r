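#' Published Zambia base-case results table
#'
#' The printed national base-case outputs for the five scenarios: patients
#' accessing testing annually, facilities reached, patients with correct
#' results, test volumes and component costs (dried testing, plasma testing,
#' facility visits, transport), and the annual system cost. These figures
#' are model *inputs* for the `"golden"` and `"anchored"` run modes of
#' [vl_model()] (arithmetic-identity checks and price sensitivity anchored
#' at the base case) and for golden-table tests.
#'
#' @return data frame with one row per scenario.
#' @export
#' @examples
#' table3_printed()[, c("scenario", "system_cost")]
table3_printed <- function() {
  data.frame(
    scenario      = c("plasma_only", "plasma_dbs", "plasma_psc", "dbs_only", "psc_only"),
    access        = c(814066, 965587, 965587, 965587, 965587),
    facilities    = c(800, 1041, 1041, 1041, 1041),
    correct       = c(795342, 920243, 929857, 856476, 884844),
    dried_specimen = c(NA, "dbs", "psc", "dbs", "psc"),
    dried_tests   = c(0, 306860, 296308, 1152640, 1108200),
    plasma_tests  = c(930982, 810283, 810283, 0, 0),
    visits        = c(931011, 1117143, 1106591, 1152640, 1108200),
    dried_cost    = c(0, 5808856, 6818046, 21819481, 25499686),
    plasma_cost   = c(17130067, 14909215, 14909215, 0, 0),
    visit_cost    = c(3398191, 4081157, 4039542, 4220251, 4045952),
    transport_cost = c(3264509, 3637168, 3637168, 2390317, 2390317),
    system_cost   = c(23792767, 28436396, 29403970, 28430050, 31935954),
    stringsAsFactors = FALSE)
}
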