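# Plain-text configuration, experiment-log CSV, fixture logs, manifest.

# key = (type, lower, upper) schema; units embedded in key names.
config_schema <- function() {
  list(
    algorithm            = list(type = "choice",
                                choices = c("oscillation", "ranking")),
    threshold            = list(type = "num", lo = 0, hi = 1, open = TRUE),
    n_euglena            = list(type = "int", lo = 1, hi = 1e6),
    n_chlamy             = list(type = "int", lo = 1, hi = 1e6),
    seed                 = list(type = "int", lo = 0, hi = 2^31 - 2),
    total_steps          = list(type = "int", lo = 1, hi = 1e6),
    warmup_steps         = list(type = "int", lo = 0, hi = 1e6),
    cooldown_steps       = list(type = "int", lo = 0, hi = 1e6),
    cycle_s              = list(type = "num", lo = 0, hi = 60, open = TRUE),
    n_subticks           = list(type = "int", lo = 1, hi = 1000),
    resolution_um_px     = list(type = "num", lo = 0, hi = 100, open = TRUE),
    sync_jitter_cycles   = list(type = "int", lo = 0, hi = 10),
    resting_fraction     = list(type = "num", lo = 0, hi = 1),
    square_width_um      = list(type = "num", lo = 0, hi = 1e5, open = TRUE),
    passage_width_um     = list(type = "num", lo = 0, hi = 1e5, open = TRUE),
    depth_um             = list(type = "num", lo = 0, hi = 1e5, open = TRUE),
    euglena_border_turn_prob   = list(type = "num", lo = 0, hi = 1),
    euglena_heading_noise      = list(type = "num", lo = 0, hi = 100),
    euglena_tumble_speed_frac  = list(type = "num", lo = 0, hi = 10),
    euglena_tumble_reorient    = list(type = "num", lo = 0, hi = 1),
    euglena_tumble_stroke_frac = list(type = "num", lo = 0, hi = 10),
    chlamy_k_act               = list(type = "num", lo = 0, hi = 100),
    chlamy_k_rest              = list(type = "num", lo = 0, hi = 100),
    chlamy_heading_noise       = list(type = "num", lo = 0, hi = 100),
    chlamy_exit_damping        = list(type = "num", lo = 0, hi = 1),
    wall_jitter                = list(type = "num", lo = 0, hi = pi),
    draw_resting               = list(type = "bool")
  )
}

#' Load an experiment configuration from a key-value file
#'
#' Reads a plain-text file of `key = value` lines (`#` starts a comment;
#' blank lines ignored), validates every key against the documented schema,
#' and returns a full [experiment_config()] with defaults filled in. An
#' empty file yields the default configuration. Unknown keys and
#' out-of-range values are rejected with descriptive errors.
#'
#' Recognized keys: `algorithm`, `threshold`, `n_euglena`, `n_chlamy`,
#' `seed`, `total_steps`, `warmup_steps`, `cooldown_steps`, `cycle_s`,
#' `n_subticks`, `resolution_um_px`, `sync_jitter_cycles`,
#' `resting_fraction`, `square_width_um`, `passage_width_um`, `depth_um`,
#' every [behavior_params()] name, `wall_jitter`, and `draw_resting`.
#'
#' @param path Path to the configuration file.
#' @return An [experiment_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  schema <- config_schema()
  unknown <- setdiff(names(kv), names(schema))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  parsed <- list()
  for (key in names(kv)) {
    sc <- schema[[key]]
    val <- kv[[key]]
    parsed[[key]] <- switch(sc$type,
      choice = {
        if (!val %in% sc$choices)
          stop(key, " must be one of: ", paste(sc$choices, collapse = ", "),
               call. = FALSE)
        val
      },
      bool = {
        b <- toupper(val) %in% c("TRUE", "T", "YES", "1")
        if (!b && !toupper(val) %in% c("FALSE", "F", "NO", "0"))
          stop(key, " must be a logical value", call. = FALSE)
        b
      },
      {
        x <- suppressWarnings(as.numeric(val))
        if (is.na(x)) stop(key, " must be numeric, got '", val, "'",
                           call. = FALSE)
        open <- isTRUE(sc$open)
        bad <- if (open) (x <= sc$lo || x >= sc$hi)
               else (x < sc$lo || x > sc$hi)
        if (bad)
          stop(key, " = ", val, " out of range ",
               if (open) "(" else "[", sc$lo, ", ", sc$hi,
               if (open) ")" else "]", call. = FALSE)
        if (sc$type == "int") {
          if (x != round(x)) stop(key, " must be an integer", call. = FALSE)
          as.integer(x)
        } else x
      })
  }

  par_names <- setdiff(names(config_schema()),
                       c("algorithm", "threshold", "n_euglena", "n_chlamy",
                         "seed", "total_steps", "warmup_steps",
                         "cooldown_steps", "cycle_s", "n_subticks",
                         "resolution_um_px", "sync_jitter_cycles",
                         "resting_fraction", "square_width_um",
                         "passage_width_um", "depth_um"))
  par_args <- parsed[intersect(names(parsed), par_names)]
  params <- do.call(behavior_params, par_args)
  lay_args <- list()
  if (!is.null(parsed$square_width_um))
    lay_args$square_width <- parsed$square_width_um
  if (!is.null(parsed$passage_width_um))
    lay_args$passage_width <- parsed$passage_width_um
  if (!is.null(parsed$depth_um)) lay_args$depth <- parsed$depth_um
  layout <- do.call(grid_layout, lay_args)

  cfg_args <- parsed[intersect(names(parsed),
                               c("algorithm", "threshold", "n_euglena",
                                 "n_chlamy", "seed", "total_steps",
                                 "warmup_steps", "cooldown_steps",
                                 "cycle_s", "n_subticks",
                                 "sync_jitter_cycles", "resting_fraction"))]
  if (!is.null(parsed$resolution_um_px))
    cfg_args$resolution <- parsed$resolution_um_px
  cfg_args$params <- params
  cfg_args$layout <- layout
  do.call(experiment_config, cfg_args)
}

#' Write a configuration to a key-value file
#'
#' Inverse of [load_config()] for the scalar keys.
#'
#' @param config An [experiment_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  lay <- config$layout
  lines <- c(
    sprintf("algorithm = %s", config$algorithm),
    sprintf("threshold = %g", config$threshold),
    sprintf("n_euglena = %d", config$n_euglena),
    sprintf("n_chlamy = %d", config$n_chlamy),
    sprintf("seed = %d", config$seed),
    sprintf("total_steps = %d", config$total_steps),
    sprintf("warmup_steps = %d", config$warmup_steps),
    sprintf("cooldown_steps = %d", config$cooldown_steps),
    sprintf("cycle_s = %g", config$cycle_s),
    sprintf("n_subticks = %d", config$n_subticks),
    sprintf("resolution_um_px = %g", config$resolution),
    sprintf("sync_jitter_cycles = %d", config$sync_jitter_cycles),
    sprintf("resting_fraction = %g", config$resting_fraction),
    sprintf("square_width_um = %g", lay$square_width),
    sprintf("passage_width_um = %g", lay$passage_width),
    sprintf("depth_um = %g", lay$depth),
    vapply(setdiff(names(p), "draw_resting"),
           function(nm) sprintf("%s = %g", nm, p[[nm]]), ""),
    sprintf("draw_resting = %s", p$draw_resting)
  )
  writeLines(lines, path)
  invisible(path)
}

pattern_mask <- function(m) {
  apply(m, 1L, function(z) paste(as.integer(z), collapse = ""))
}

mask_pattern <- function(s) {
  t(vapply(strsplit(s, ""), function(z) as.integer(z) == 1L, logical(25)))
}

#' Write an experiment log to CSV
#'
#' Long format, two rows per time step (one per dish):
#' `step, time_s, dish, lit_mask, tm_1..tm_25, ratio, flip_event`, where
#' `lit_mask` is the 25-character 0/1 illumination mask and `flip_event` is
#' the new lit group at steps where that dish's illumination flipped, empty
#' otherwise.
#'
#' @param log An `aq_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(log, path) {
  n <- length(log$step)
  mk <- function(dish, pat, tm, ratio) {
    fe <- character(n)
    f <- log$flips[log$flips$dish == dish, , drop = FALSE]
    fe[f$step] <- f$group
    tmdf <- as.data.frame(tm)
    names(tmdf) <- paste0("tm_", 1:25)
    cbind(data.frame(step = log$step, time_s = log$time_s, dish = dish,
                     lit_mask = pattern_mask(pat),
                     stringsAsFactors = FALSE),
          tmdf,
          data.frame(ratio = ratio, flip_event = fe,
                     stringsAsFactors = FALSE))
  }
  out <- rbind(mk("A", log$patternA, log$tmA, log$ratioA),
               mk("B", log$patternB, log$tmB, log$ratioB))
  out <- out[order(out$step, out$dish), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment log from CSV
#'
#' Reconstructs an `aq_log` written by [write_log_csv()]. The schedule
#' (warmup/cooldown) needed by the windowed metrics is taken from `config`;
#' by default the standard schedule is assumed scaled to the number of steps
#' found.
#'
#' @param path CSV path.
#' @param config Optional [experiment_config()] describing the run.
#' @return An `aq_log`.
#' @export
read_log_csv <- function(path, config = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(lit_mask = "character"))
  need <- c("step", "time_s", "dish", "lit_mask", paste0("tm_", 1:25),
            "ratio", "flip_event")
  if (!all(need %in% names(d)))
    stop("not an experiment-log CSV: missing columns", call. = FALSE)
  d$flip_event <- as.character(d$flip_event)
  d$flip_event[is.na(d$flip_event)] <- ""
  a <- d[d$dish == "A", , drop = FALSE]; a <- a[order(a$step), ]
  b <- d[d$dish == "B", , drop = FALSE]; b <- b[order(b$step), ]
  n <- nrow(a)
  cyc <- if (n > 1L) a$time_s[2] - a$time_s[1] else a$time_s[1]
  if (is.null(config)) {
    wu <- min(500L, max(0L, n %/% 8L))
    config <- experiment_config(total_steps = n, warmup_steps = wu,
                                cooldown_steps = wu, cycle_s = cyc)
  }
  fa <- nzchar(a$flip_event); fb <- nzchar(b$flip_event)
  fl <- rbind(
    data.frame(step = a$step[fa], dish = rep("A", sum(fa)),
               group = a$flip_event[fa], stringsAsFactors = FALSE),
    data.frame(step = b$step[fb], dish = rep("B", sum(fb)),
               group = b$flip_event[fb], stringsAsFactors = FALSE))
  fl$time_s <- fl$step * cyc
  fl <- fl[order(fl$step), c("step", "time_s", "dish", "group")]
  tmcols <- paste0("tm_", 1:25)
  structure(list(step = a$step, time_s = a$time_s,
                 patternA = mask_pattern(a$lit_mask),
                 patternB = mask_pattern(b$lit_mask),
                 tmA = as.matrix(a[, tmcols]), tmB = as.matrix(b[, tmcols]),
                 ratioA = a$ratio, ratioB = b$ratio,
                 flips = fl, config = config),
            class = "aq_log")
}

#' Construct synthetic fixture logs with known ground truth
#'
#' Builds experiment logs whose oscillation period, phase delay and pattern
#' statistics are known by construction, so the analysis functions can be
#' tested without running the simulator.
#'
#' Scenarios:
#' * `perfect_oscillation` - dish B flips groups at perfectly regular
#'   intervals and dish A follows after a fixed delay. Times are quantized
#'   to the cycle grid; the achieved (quantized) period and delay are
#'   returned in the `truth` attribute.
#' * `fixed_pattern` - one constant 12-square pattern in both dishes for
#'   the whole feedback window.
#' * `random_patterns` - independent uniformly drawn 12-square patterns in
#'   each dish at every feedback step.
#'
#' @param scenario One of the above.
#' @param period_min,delay_min Oscillation targets, minutes.
#' @param total_steps,warmup_steps,cooldown_steps,cycle_s Schedule.
#' @param seed RNG seed (used by `random_patterns`).
#' @return An `aq_log` with attribute `truth` (list of the constructed
#'   metric values).
#' @export
make_fixture_log <- function(scenario = c("perfect_oscillation",
                                          "fixed_pattern",
                                          "random_patterns"),
                             period_min = 6.5, delay_min = 0.43,
                             total_steps = 4000L, warmup_steps = 500L,
                             cooldown_steps = 500L, cycle_s = 1.47,
                             seed = 1L) {
  scenario <- match.arg(scenario)
  lay <- grid_layout()
  cfg <- experiment_config(total_steps = total_steps,
                           warmup_steps = warmup_steps,
                           cooldown_steps = cooldown_steps,
                           cycle_s = cycle_s, seed = seed)
  N <- total_steps
  fb <- seq.int(warmup_steps + 1L, N - cooldown_steps)
  patA <- matrix(FALSE, N, 25L); patB <- matrix(FALSE, N, 25L)
  flips <- data.frame(step = integer(), time_s = numeric(),
                      dish = character(), group = character(),
                      stringsAsFactors = FALSE)
  truth <- list()

  if (scenario == "perfect_oscillation") {
    half <- max(1L, round(period_min * 60 / cycle_s / 2))
    dly <- max(1L, round(delay_min * 60 / cycle_s))
    stopifnot(dly < half)
    truth$period_min <- 2 * half * cycle_s / 60
    truth$delay_min <- dly * cycle_s / 60
    grpB <- grpA <- "I"
    bsteps <- seq.int(fb[1] + half, max(fb) - dly, by = half)
    for (i in seq_along(bsteps)) {
      g <- if (i %% 2L == 1L) "II" else "I"
      flips <- rbind(flips,
                     data.frame(step = bsteps[i],
                                time_s = bsteps[i] * cycle_s, dish = "B",
                                group = g, stringsAsFactors = FALSE),
                     data.frame(step = bsteps[i] + dly,
                                time_s = (bsteps[i] + dly) * cycle_s,
                                dish = "A", group = g,
                                stringsAsFactors = FALSE))
    }
    flips <- flips[order(flips$step), , drop = FALSE]
    gB <- gA <- rep("I", N)
    for (i in seq_len(nrow(flips))) {
      f <- flips[i, ]
      if (f$dish == "B") gB[f$step:N] <- f$group else gA[f$step:N] <- f$group
    }
    for (s in fb) {
      patA[s, ] <- group_pattern(gA[s], lay)
      patB[s, ] <- group_pattern(gB[s], lay)
    }
  } else if (scenario == "fixed_pattern") {
    p <- logical(25); p[1:12] <- TRUE
    patA[fb, ] <- matrix(p, length(fb), 25L, byrow = TRUE)
    patB[fb, ] <- matrix(p, length(fb), 25L, byrow = TRUE)
    truth$pattern <- paste(as.integer(p), collapse = "")
    truth$count <- length(fb)
  } else {
    set.seed(seed)
    for (s in fb) {
      pa <- logical(25); pa[sample.int(25L, 12L)] <- TRUE
      pb <- logical(25); pb[sample.int(25L, 12L)] <- TRUE
      patA[s, ] <- pa; patB[s, ] <- pb
    }
  }

  log <- structure(list(step = seq_len(N), time_s = seq_len(N) * cycle_s,
                        patternA = patA, patternB = patB,
                        tmA = matrix(0L, N, 25L), tmB = matrix(0L, N, 25L),
                        ratioA = rep(NA_real_, N),
                        ratioB = rep(NA_real_, N),
                        flips = flips, config = cfg),
                   class = "aq_log")
  attr(log, "truth") <- truth
  log
}

#' Write a run manifest
#'
#' Records the configuration snapshot, master seed, package version, and an
#' inventory of the run's output files with MD5 checksums, sufficient to
#' re-run the experiment bit-identically.
#'
#' @param config An [experiment_config()] object.
#' @param files Character vector of output file paths.
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  sums <- tools::md5sum(files)
  lines <- c("# microlink run manifest",
             sprintf("package_version = %s",
                     as.character(utils::packageVersion("microlink"))),
             sprintf("master_seed = %d", config$seed),
             "",
             "[config]",
             readLines(write_config(config, tempfile())),
             "",
             "[files]",
             sprintf("%s = %s", basename(files), unname(sums)))
  writeLines(lines, path)
  invisible(path)
}
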