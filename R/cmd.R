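#' Region command: curves, grid classification and chart for one alpha3
#'
#' Writes `curves.csv` (schema `branch,k,alpha3,omega,alpha1,alpha2`; L, C0
#' and \eqn{C_k^\pm} up to `k_max`), `grid.csv` (schema
#' `alpha1,alpha2,alpha3,stable,n_unstable`, counts from the
#' argument-principle oracle) and `region.png` into `out_dir`.
#'
#' @inheritParams plot_region
#' @param n grid resolution per axis.
#' @param out_dir output directory (created if needed).
#' @param k_max largest curve branch index.
#' @return named character vector of the files written, invisibly.
#' @export
cmd_region <- function(alpha3, window = c(-6, 6, -6, 6), n = 41,
                       out_dir = ".", k_max = 3) {
  check_alpha3(alpha3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- build_all_curves(alpha3, k_max = k_max,
                             alpha1_range = window[1:2] + c(-1, 1))
  grid <- tidyr::expand_grid(
    alpha1 = seq(window[1], window[2], length.out = n),
    alpha2 = seq(window[3], window[4], length.out = n)
  )
  cls <- classify_grid(grid, alpha3, count = TRUE)
  files <- c(
    curves = file.path(out_dir, "curves.csv"),
    grid = file.path(out_dir, "grid.csv"),
    chart = file.path(out_dir, "region.png")
  )
  readr::write_csv(curves, files["curves"])
  readr::write_csv(
    cls[, c("alpha1", "alpha2", "alpha3", "stable", "n_unstable")],
    files["grid"]
  )
  p <- plot_region(alpha3, grid = cls, k_max = k_max, window = window)
  ggplot2::ggsave(files["chart"], p, width = 7, height = 6, dpi = 120)
  invisible(files)
}

#' Animation frames of the moving stability chart
#'
#' Renders one PNG per value of \eqn{\alpha_3} on a fixed window with
#' constant axes, zero-padded filenames (`frame_000.png`, ...), suitable for
#' assembly into a movie of the chart deforming as \eqn{\alpha_3} sweeps
#' from near -1 to near +1.
#'
#' @param alpha3_min,alpha3_max sweep range, inside (-1, 1).
#' @param frames number of frames, at least 2.
#' @param out_dir output directory.
#' @param window fixed plotting window.
#' @return character vector of the files written, invisibly.
#' @export
cmd_animate <- function(alpha3_min, alpha3_max, frames, out_dir = ".",
                        window = c(-8, 8, -8, 8)) {
  check_alpha3(alpha3_min)
  check_alpha3(alpha3_max)
  if (!is.numeric(frames) || frames < 2) {
    rlang::abort("`frames` must be at least 2",
                 class = "delaychart_error_precondition")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a3s <- seq(alpha3_min, alpha3_max, length.out = frames)
  files <- file.path(out_dir, sprintf("frame_%03d.png", seq_len(frames) - 1))
  for (i in seq_along(a3s)) {
    p <- plot_region(a3s[i], window = window)
    ggplot2::ggsave(files[i], p, width = 7, height = 6, dpi = 100)
  }
  invisible(files)
}

#' Model command: reports from a model configuration file
#'
#' Reads a model config (see [read_model_config()]) and executes one
#' subcommand, writing its report(s) into `out_dir`:
#'
#' * `"steady-state"`: `steady_state.json` with the steady state, derived
#'   quantities and linearisation coefficients.
#' * `"alphas"`: `alphas.json` with the coefficient triple.
#' * `"classify"`: `classify.json` with the stability verdict.
#' * `"theta-study"`: `theta_study.json` (Hopf frequency, critical abscissa,
#'   theta_crit or null) and `theta_path.csv`.
#' * `"map-boundary"`: `map_<case>.csv` for the C0 and C1_plus images plus a
#'   `map_<case>.png` chart; `case` selects the regulated mechanism.
#' * `"simulate"`: `trajectory.csv` (schema `t,p,Q,E`) and
#'   `dominant_mode.json`; the history is the steady state perturbed by
#'   `amplitude`.
#'
#' @param config_path path to a JSON/YAML model config.
#' @param subcommand one of the strings above.
#' @param out_dir output directory.
#' @param case mechanism for `map-boundary` (`"g"` or `"beta1"`).
#' @param t_end,N,amplitude simulation controls for `simulate`.
#' @return named character vector of files written, invisibly.
#' @export
cmd_model <- function(config_path,
                      subcommand = c("steady-state", "alphas", "classify",
                                     "theta-study", "map-boundary",
                                     "simulate"),
                      out_dir = ".", case = c("g", "beta1"),
                      t_end = 200, N = 256, amplitude = 0.01) {
  subcommand <- rlang::arg_match(subcommand)
  case <- rlang::arg_match(case)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- read_model_config(config_path)
  ss <- solve_steady_state(model)
  co <- linearization_coeffs(model, ss)
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    stats::setNames(file.path(out_dir, f), sub("\\.json$", "", f))
  }

  files <- switch(subcommand,
    "steady-state" = wj(c(unclass(ss), co), "steady_state.json"),
    "alphas" = wj(co, "alphas.json"),
    "classify" = {
      v <- classify_point(co$alpha1, co$alpha2, co$alpha3)
      wj(list(stable = v$stable, note = v$note,
              alpha1 = co$alpha1, alpha2 = co$alpha2, alpha3 = co$alpha3),
         "classify.json")
    },
    "theta-study" = {
      hp <- hopf_point(model, ss)
      tc <- theta_crit(model, ss)
      path <- theta_path(model, ss)
      f1 <- wj(list(omega_star = hp$omega_star, alpha1_bar = hp$alpha1_bar,
                    alpha1_at_half = -model$death_rate -
                      model$G$value(ss$Ebar),
                    theta_crit = if (is.na(tc)) NULL else tc),
               "theta_study.json")
      f2 <- file.path(out_dir, "theta_path.csv")
      readr::write_csv(path, f2)
      c(f1, theta_path = f2)
    },
    "map-boundary" = {
      long_case <- if (case == "g") "g_regulated" else "beta1_regulated"
      c0 <- build_curve("C0", 0, co$alpha3, n = 401,
                        alpha1_range = c(-40, 2))
      c1p <- build_curve("Ck_plus", 1, co$alpha3, n = 401,
                         alpha1_range = c(-40, 40))
      mapped <- dplyr::bind_rows(
        map_to_model_plane(c0, model, ss, case = long_case),
        map_to_model_plane(c1p, model, ss, case = long_case)
      )
      f1 <- file.path(out_dir, paste0("map_", case, ".csv"))
      readr::write_csv(mapped, f1)
      f2 <- file.path(out_dir, paste0("map_", case, ".png"))
      ggplot2::ggsave(f2, plot_model_plane(mapped), width = 7, height = 5,
                      dpi = 120)
      c(map = f1, chart = f2)
    },
    "simulate" = {
      traj <- integrate_model(model, history_steady_state(ss, amplitude),
                              t_end = t_end, N = N)
      f1 <- file.path(out_dir, "trajectory.csv")
      readr::write_csv(tibble::as_tibble(traj), f1)
      mode <- tryCatch(
        measure_dominant_mode(traj, center = ss$Qbar, t_min = t_end / 4),
        error = function(e) list(rate = NA_real_, freq = NA_real_)
      )
      f2 <- wj(mode, "dominant_mode.json")
      c(trajectory = f1, f2)
    }
  )
  invisible(files)
}
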