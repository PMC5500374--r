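# Example instances in the style of the model's illustrative figures.
# Figure graphs are not hand-transcribed; each fixture is FOUND ONCE by
# the SAT engine under the style constraints stated in its name
# (compartment count, molecule count, regime, underlying connectivity)
# and stored as JSON under inst/extdata. The captions' connectivity
# claims are the checked contract.

fixture_styles <- function() list(
  row2_two_compartment = list(
    nodes = 2, M = 6, regime = regime_row(2),
    connectivity = list(type = "exact", k = 3L)),
  row3_two_compartment = list(
    nodes = 2, M = 6, regime = regime_row(3),
    connectivity = list(type = "exact", k = 4L)),
  three_connected_four_molecule = list(
    nodes = 3, M = 4, regime = regime_row(1),
    connectivity = list(type = "exact", k = 3L)))

#' Search for a style-constrained fixture with the SAT engine
#'
#' @param name one of `"row2_two_compartment"`,
#'   `"row3_two_compartment"`, `"three_connected_four_molecule"`.
#' @param seed solver seed.
#' @return a validated [network_instance()].
#' @export
fixture_search <- function(name, seed = 0) {
  st <- fixture_styles()[[match.arg(name, names(fixture_styles()))]]
  b <- search_bounds(st$nodes, st$M, connectivity = st$connectivity,
                     strongly_connected_only = TRUE)
  enc <- encode_feasibility(b, st$regime, nodes = st$nodes)
  v <- solve_cnf(enc$cnf, seed = seed)
  if (v$status != "SAT")
    stop("fixture search failed for style '", name,
         "': the constrained encoding is unsatisfiable (encoding bug?)")
  inst <- decode_instance(v, enc)
  val <- validate_instance(inst)
  if (!val$pass)
    stop("fixture for '", name, "' fails validation (encoding bug): ",
         paste(val$violations, collapse = "; "))
  inst
}

#' Load a bundled example instance
#'
#' Fixtures were generated by [fixture_search()] and shipped as JSON.
#'
#' @inheritParams fixture_search
#' @return a [network_instance()].
#' @export
build_fixture <- function(name) {
  name <- match.arg(name, names(fixture_styles()))
  path <- system.file("extdata", paste0(name, ".json"), package = "snaresat")
  if (!nzchar(path))
    stop("bundled fixture not found: ", name)
  read_instance(path)
}
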