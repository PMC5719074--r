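#' Reference fixtures with known ground truth
#'
#' Named parameter sets used as simulation truth throughout the package.
#' The two-state sets carry the equilibrium and kinetic binding constants of
#' the porphyrin/20S first-cluster analysis (human, wild-type yeast, and the
#' permanently open alpha-3-deltaN yeast mutant, which binds without
#' cooperativity); the kinetic-assay sets describe the chymotrypsin-like
#' dose-response, the Suc-LLVY-AMC inhibition grid, and a two-phase
#' stopped-flow trace; the structural sets describe toy complexes with
#' planted ionic contacts.  [simulate_fixture()] turns a fixture into a
#' dataset; the same name and seed always give identical output.
#'
#' @return `fixtures()` returns the registry names.  `fixture(name)` returns
#'   the fixture: a list with `name`, `params` and a `kind` tag.
#' @export
fixtures <- function() names(.fixture_registry)

.fixture_registry <- list(
  # first-cluster two-state constants (simulation truth)
  `human-20s` = list(kind = "two_state", params = list(
    K_o = 1.8e7, K_c = 7.0e3, k_o = 2.8e6, k_c = 1.3e2,
    k_off = 0.22, L = 4.0e-6, n = 3L, label = "human")),
  `yeast-20s` = list(kind = "two_state", params = list(
    K_o = 1.8e7, K_c = 7.0e3, k_o = 7.0e6, k_c = 1.3e2,
    k_off = 1.06, L = 4.0e-6, n = 3L, label = "yeast")),
  `alpha3dn` = list(kind = "two_state", params = list(
    K_o = 3.6e5, k_o = 2.5e6, k_off = 7.0, n = 1L, label = "alpha-3dN")),
  # chymotrypsin-like dose-response: IC50 ~ 2 uM
  `chtl-dose` = list(kind = "dose_response", params = list(
    ic50 = 2, hill = 1, i_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, 32),
    noise_cv = 0.03)),
  # Suc-LLVY-AMC substrate grid, pure non-competitive truth (alpha = 1)
  `sucllvy-inhibition` = list(kind = "michaelis", params = list(
    mechanism = "noncompetitive", Vmax = 1, Km = 70, Ki = 2,
    s_grid = c(10, 25, 50, 100, 150, 200),
    i_grid = c(0, 2, 6, 15, 40, 100), noise_cv = 0.03)),
  # Soret-band (421 nm) trace: fast hyperchromic then slow hypochromic phase
  `stopped-flow` = list(kind = "progress_curve", params = list(
    phases = list(c(amplitude = -0.05, rate = 10.4),
                  c(amplitude = +0.03, rate = 1.0)),
    offset = 1.0, t_grid = exp(seq(log(1e-3), log(5), length.out = 300)),
    noise_sd = 0.002,
    wavelength_nm = 421, porph_conc = 5e-6, enzyme_conc = 1e-9)),
  `toy-complex` = list(kind = "toy_complex", params = list(
    pairs = data.frame(negative = c("GLU", "ASP", "GLU"),
                       positive = c("LYS", "ARG", "LYS"),
                       distance = c(3.0, 3.5, 3.9)),
    decoys = 5L)),
  `pseudo-ring` = list(kind = "pseudo_ring", params = list(
    n_subunits = 7L, square_side = 17))
)

#' @rdname fixtures
#' @param name Fixture name, one of `fixtures()`.
#' @export
fixture <- function(name) {
  if (!name %in% names(.fixture_registry))
    stop(sprintf("unknown fixture '%s'; see fixtures()", name), call. = FALSE)
  c(list(name = name), .fixture_registry[[name]])
}

#' @rdname fixtures
#' @param seed Integer seed; the same name and seed reproduce the dataset
#'   exactly.
#' @param ... Overrides for individual fixture parameters (e.g. `noise_cv`).
#' @return `simulate_fixture()` returns the generated dataset: a
#'   `kobs_series` for two-state sets, a `michaelis_dataset`,
#'   `dose_response` or `progress_curve` for the assay sets, and PDB text
#'   (class `pdb_text`) for the structural sets.
#' @export
simulate_fixture <- function(name, seed, ...) {
  fx <- fixture(name)
  p <- utils::modifyList(fx$params, list(...))
  switch(fx$kind,
    two_state = {
      tp <- do.call(two_state_params, p[setdiff(names(p), c("x_grid", "noise_cv"))])
      gen_kobs_series(tp, x_grid = p$x_grid %||% logspace(0.2e-6, 100e-6, 15),
                      noise_cv = p$noise_cv %||% 0.05, seed = seed)
    },
    dose_response = gen_dose_response(p$ic50, p$hill, p$i_grid, p$noise_cv, seed),
    michaelis = gen_michaelis(p$mechanism,
                              list(Vmax = p$Vmax, Km = p$Km, Ki = p$Ki,
                                   alpha = p$alpha %||% NULL),
                              p$s_grid, p$i_grid, p$noise_cv, seed),
    progress_curve = gen_progress_curve(p$phases, p$offset, p$t_grid,
                                        p$noise_sd, seed,
                                        wavelength_nm = p$wavelength_nm,
                                        porph_conc = p$porph_conc,
                                        enzyme_conc = p$enzyme_conc),
    toy_complex = gen_toy_complex(p$pairs, decoys = p$decoys, seed = seed),
    pseudo_ring = gen_pseudo_ring(p$n_subunits, p$square_side, seed = seed)
  )
}

#' Two-state parameter set of a reference fixture
#'
#' Convenience accessor returning the [two_state_params()] object of one of
#' the two-state fixtures (`"human-20s"`, `"yeast-20s"`, `"alpha3dn"`).
#'
#' @param name Fixture name.
#' @return A `two_state_params` object.
#' @export
fixture_params <- function(name) {
  fx <- fixture(name)
  if (fx$kind != "two_state")
    stop(sprintf("fixture '%s' is not a two-state set", name), call. = FALSE)
  do.call(two_state_params, fx$params)
}
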