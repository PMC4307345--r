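#' Full run configuration
#'
#' Aggregates everything a simulation needs: tissue properties, the
#' perfusion model, domain geometry, boundary and initial conditions,
#' time-stepping controls, collocation counts and output requests. All
#' lengths are SI metres internally; [load_config()] accepts millimetre
#' input and converts on load.
#'
#' @param properties a [tissue_properties()]
#' @param perfusion a [perfusion_model()]
#' @param domain a [domain_spec()]
#' @param bc a [boundary_conditions()]
#' @param initial list with `T0`: uniform initial absolute temperature
#'   (degC); defaults to the arterial temperature T_b (tissue starting at
#'   body temperature)
#' @param stepping a [step_parameters()]
#' @param collocation list of [build_collocation()] arguments: `nx_int`,
#'   `ny_int`, `n_edge`, `source_offset`
#' @param output list with `snapshot_times` (s), and either `probes` (a
#'   2-column matrix of evaluation points) or `n_probes` (count of
#'   uniformly spaced centerline probes, default 121)
#' @param cond_warn condition-estimate warning threshold for the
#'   collocation solve
#' @return an object of class `bioheat_config`
#' @export
bioheat_config <- function(properties = tissue_properties(),
                           perfusion = perfusion_model("linear", a1 = 0.0005, a2 = 0.0001),
                           domain = domain_spec(),
                           bc = boundary_conditions(),
                           initial = list(),
                           stepping = step_parameters(),
                           collocation = list(),
                           output = list(),
                           cond_warn = 1e12) {
  stopifnot(inherits(properties, "tissue_properties"),
            inherits(perfusion, "perfusion_model"),
            inherits(domain, "domain_spec"),
            inherits(bc, "boundary_conditions"),
            inherits(stepping, "step_parameters"))
  initial <- check_keys(initial, "initial", c("T0"))
  if (is.null(initial$T0)) initial$T0 <- properties$T_b
  if (any(!is.finite(initial$T0))) stop("initial T0 must be finite", call. = FALSE)
  collocation <- check_keys(collocation, "collocation",
                            c("nx_int", "ny_int", "n_edge", "source_offset"))
  collocation <- modifyList(
    list(nx_int = 9, ny_int = 7, n_edge = c(9, 7, 7, 9), source_offset = 1.5),
    collocation)
  output <- check_keys(output, "output", c("snapshot_times", "probes", "n_probes"))
  output <- modifyList(list(snapshot_times = numeric(0), n_probes = 121), output,
                       keep.null = TRUE)
  structure(
    list(properties = properties, perfusion = perfusion, domain = domain,
         bc = bc, initial = initial, stepping = stepping,
         collocation = collocation, output = output, cond_warn = cond_warn),
    class = "bioheat_config"
  )
}

check_keys <- function(x, section, allowed) {
  if (is.null(x)) return(list())
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

config_probes <- function(config) {
  if (!is.null(config$output$probes)) return(rbind(config$output$probes))
  n <- config$output$n_probes
  cbind(seq(0, config$domain$Lx, length.out = n),
        rep(config$domain$Ly / 2, n))
}

#' @export
print.bioheat_config <- function(x, ...) {
  cat("Bioheat run configuration\n")
  print(x$domain); print(x$perfusion); print(x$bc)
  cat(sprintf("  initial T0 = %g degC; dt = %g s, t_end = %g s\n",
              x$initial$T0[1], x$stepping$dt, x$stepping$t_end))
  cat(sprintf("  collocation: %d x %d interior, %s boundary, source offset %g\n",
              x$collocation$nx_int, x$collocation$ny_int,
              paste(x$collocation$n_edge, collapse = "+"),
              x$collocation$source_offset))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Every section is optional; omitted fields fall back to the standard
#' skin-model defaults (Table-style property values, linear perfusion
#' a1 = 0.0005, a2 = 0.0001, a 30 mm x 15 mm domain, 25/37 degC boundary
#' temperatures). Defaulted sections are logged. Domain lengths may be
#' given in millimetres by setting `domain: {units: mm}`. Unknown keys
#' anywhere are an error naming the key.
#'
#' @param path path to a YAML configuration file
#' @param quiet suppress the defaulted-field log
#' @return a [bioheat_config()]
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  raw <- check_keys(raw, "config",
                    c("properties", "perfusion", "domain", "bc", "initial",
                      "stepping", "collocation", "output", "cond_warn"))
  log_default <- function(what) {
    if (!quiet) message("config: using defaults for ", what)
  }

  props <- if (is.null(raw$properties)) {
    log_default("properties"); tissue_properties()
  } else {
    a <- check_keys(raw$properties, "properties",
                    c("k", "rho", "c", "rho_b", "c_b", "T_b", "Q_r", "Q_m"))
    miss <- setdiff(c("k", "rho", "c", "rho_b", "c_b", "T_b", "Q_r", "Q_m"), names(a))
    if (length(miss)) log_default(paste("properties:", paste(miss, collapse = ", ")))
    do.call(tissue_properties, a)
  }

  perf <- if (is.null(raw$perfusion)) {
    log_default("perfusion"); perfusion_model("linear", a1 = 0.0005, a2 = 0.0001)
  } else {
    a <- check_keys(raw$perfusion, "perfusion", c("kind", "a1", "a2"))
    if (is.null(a$kind) || is.null(a$a1)) {
      stop("perfusion section requires 'kind' and 'a1'", call. = FALSE)
    }
    perfusion_model(a$kind, a$a1, if (is.null(a$a2)) 0 else a$a2)
  }

  dom <- if (is.null(raw$domain)) {
    log_default("domain"); domain_spec()
  } else {
    a <- check_keys(raw$domain, "domain", c("Lx", "Ly", "units"))
    units <- if (is.null(a$units)) "m" else a$units
    if (!units %in% c("m", "mm")) stop("domain units must be 'm' or 'mm'", call. = FALSE)
    s <- if (units == "mm") 1e-3 else 1
    domain_spec(Lx = if (is.null(a$Lx)) 0.03 else a$Lx * s,
                Ly = if (is.null(a$Ly)) 0.015 else a$Ly * s)
  }

  bcs <- if (is.null(raw$bc)) {
    log_default("bc"); boundary_conditions()
  } else {
    a <- check_keys(raw$bc, "bc", c("T_s", "T_c"))
    do.call(boundary_conditions, a)
  }

  stepping <- if (is.null(raw$stepping)) {
    log_default("stepping"); step_parameters()
  } else {
    a <- check_keys(raw$stepping, "stepping",
                    c("dt", "t_end", "steady_tol", "steady_hold"))
    do.call(step_parameters, a)
  }

  coll <- raw$collocation
  if (!is.null(coll) && !is.null(coll$n_edge)) coll$n_edge <- unlist(coll$n_edge)
  out <- raw$output
  if (!is.null(out) && !is.null(out$snapshot_times)) {
    out$snapshot_times <- unlist(out$snapshot_times)
  }

  bioheat_config(properties = props, perfusion = perf, domain = dom, bc = bcs,
                 initial = if (is.null(raw$initial)) list() else raw$initial,
                 stepping = stepping,
                 collocation = if (is.null(coll)) list() else coll,
                 output = if (is.null(out)) list() else out,
                 cond_warn = if (is.null(raw$cond_warn)) 1e12 else raw$cond_warn)
}

#' Write the effective configuration back to YAML
#'
#' Dumping and re-loading reproduces an identical run (round-trip
#' invariant; the solver itself contains no randomness).
#'
#' @param config a [bioheat_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "bioheat_config"))
  p <- config$properties
  lst <- list(
    properties = p[c("k", "rho", "c", "rho_b", "c_b", "T_b", "Q_r", "Q_m")],
    perfusion = unclass(config$perfusion),
    domain = list(Lx = config$domain$Lx, Ly = config$domain$Ly, units = "m"),
    bc = unclass(config$bc),
    initial = config$initial,
    stepping = unclass(config$stepping),
    collocation = config$collocation,
    output = list(snapshot_times = config$output$snapshot_times,
                  n_probes = config$output$n_probes),
    cond_warn = config$cond_warn
  )
  writeLines(yaml::as.yaml(lst), path)
  invisible(path)
}

#' Write recorded snapshots as CSV
#'
#' One row per (time, tracked point); columns `t_s`, `role`, `x_mm`,
#' `y_mm`, `T_C`. Temperatures are absolute.
#'
#' @param record a `run_record`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_snapshots <- function(record, path) {
  stopifnot(inherits(record, "run_record"))
  rows <- do.call(rbind, lapply(seq_along(record$times), function(i) {
    data.frame(t_s = record$times[i], role = record$points$role,
               x_mm = 1000 * record$points$x, y_mm = 1000 * record$points$y,
               T_C = record$snapshots[i, ])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

write_profiles <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(label = attr(cv, "label"), t_s = attr(cv, "t"),
               x_mm = 1000 * cv$x, T_C = cv$T)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{solve}{run the meshless march and write `snapshots.csv`}
#'   \item{reference}{run the finite-difference reference, write
#'     `reference_snapshots.csv`}
#'   \item{verify}{run both, write `verification.csv` (per-time relative
#'     errors) and print the maximum}
#'   \item{sweep}{run a coefficient sensitivity sweep
#'     (`--parameter=a1 --values=0.005,0.0005`), write `sweep_profiles.csv`
#'     and `sweep_summary.csv`}
#' }
#' Options: `--config=FILE` (YAML, optional: defaults throughout),
#' `--out=DIR` (default `.`), `--parameter`, `--values`. The solver is
#' fully deterministic: repeated invocations write byte-identical output.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code, 0 on success
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: bioheat <solve|reference|verify|sweep> [--config=FILE] [--out=DIR] [--parameter=a1|a2] [--values=v1,v2,...]"
  fail <- function(...) { message(...); 1L }
  if (!length(argv)) return(fail(usage))
  cmd <- argv[1]
  if (!cmd %in% c("solve", "reference", "verify", "sweep")) {
    return(fail("unknown subcommand '", cmd, "'\n", usage))
  }
  opts <- list(out = ".")
  for (a in argv[-1]) {
    m <- regmatches(a, regexec("^--([a-z]+)=(.*)$", a))[[1]]
    if (length(m) != 3L) return(fail("cannot parse argument '", a, "'\n", usage))
    opts[[m[2]]] <- m[3]
  }
  res <- tryCatch({
    config <- if (!is.null(opts$config)) load_config(opts$config) else bioheat_config()
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    message(sprintf("lambda2 = %g 1/m^2",
                    helmholtz_lambda2(config$properties, config$stepping$dt)))
    switch(cmd,
      solve = {
        rec <- march(config)
        message(sprintf("condition estimate %.3g; %d steps run",
                        rec$diagnostics$condition, length(rec$change)))
        write_snapshots(rec, file.path(opts$out, "snapshots.csv"))
      },
      reference = {
        rec <- fd_march(config)
        write_snapshots(rec, file.path(opts$out, "reference_snapshots.csv"))
      },
      verify = {
        v <- verify_against_reference(config)
        df <- data.frame(t_s = config$output$snapshot_times,
                         rel_error_pct = as.numeric(v$errors))
        write.csv(df, file.path(opts$out, "verification.csv"), row.names = FALSE)
        message(sprintf("max relative error vs reference: %.4f%%", v$max_error))
        if (v$max_error > 0.5) stop("verification failed: error above 0.5%")
      },
      sweep = {
        if (is.null(opts$parameter) || is.null(opts$values)) {
          stop("sweep requires --parameter and --values")
        }
        values <- as.numeric(strsplit(opts$values, ",")[[1]])
        sw <- sensitivity_sweep(config, opts$parameter, values)
        write_profiles(sw$curves, file.path(opts$out, "sweep_profiles.csv"))
        summ <- data.frame(
          parameter = sw$parameter, value = sw$values,
          steady_time_s = sw$steady_times,
          intersection_x_mm = if (is.list(sw$intersection)) 1000 * sw$intersection$x else NA,
          intersection_T_C = if (is.list(sw$intersection)) sw$intersection$T else NA)
        write.csv(summ, file.path(opts$out, "sweep_summary.csv"), row.names = FALSE)
        print(sw)
      })
    0L
  }, error = function(e) fail("error: ", conditionMessage(e)))
  invisible(res)
}
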