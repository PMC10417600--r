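#' Experimental design of the preference trial
#'
#' Builds the rotation of light colors over compartments crossed with thermal
#' conditions: nine experiments -- three thermal environments (hot 35 degC,
#' neutral 24 degC, cold 17 degC), each with the three Latin-square light
#' rotations WGR, RWG, GRW over compartments A, B, C -- so that every light
#' color appears in every compartment exactly once per thermal condition.
#' Each experiment lasts \code{days_per_treatment} days and the whole block is
#' repeated \code{replicates} times.
#'
#' @param days_per_treatment days each experiment runs before rotation
#'   (default 2).
#' @param replicates number of times the 9-experiment block is repeated
#'   (default 3).
#' @param flock_size number of hens sharing the chamber (default 6).
#' @return an \code{epc_design}: a long data frame with one row per
#'   (experiment, compartment) holding \code{experiment_id}, \code{thermal},
#'   \code{temperature_c}, \code{compartment} and \code{light}, with the
#'   schedule parameters stored as attributes.
#' @export
epc_design <- function(days_per_treatment = 2L, replicates = 3L,
                       flock_size = 6L) {
  rotations <- list(c("white", "green", "red"),
                    c("red", "white", "green"),
                    c("green", "red", "white"))
  thermal <- c("hot", "neutral", "cold")
  temp_c <- c(hot = 35, neutral = 24, cold = 17)
  rows <- do.call(rbind, lapply(1:9, function(e) {
    th <- thermal[ceiling(e / 3)]
    data.frame(experiment_id = e, thermal = th,
               temperature_c = unname(temp_c[th]),
               compartment = c("A", "B", "C"),
               light = rotations[[(e - 1) %% 3 + 1]])
  }))
  design <- structure(rows,
                      days_per_treatment = as.integer(days_per_treatment),
                      replicates = as.integer(replicates),
                      flock_size = as.integer(flock_size),
                      class = c("epc_design", "data.frame"))
  validate_design(design)
  design
}

validate_design <- function(design) {
  tab <- table(design$thermal, design$compartment, design$light)
  if (any(tab != 1))
    stop("invalid design: every light must appear in every compartment ",
         "exactly once per thermal condition")
  invisible(design)
}

#' @export
print.epc_design <- function(x, ...) {
  cat(sprintf("<epc_design> %d experiments x %d day(s) x %d replicate(s) = %d days; flock of %d\n",
              length(unique(x$experiment_id)), attr(x, "days_per_treatment"),
              attr(x, "replicates"), schedule_days(x), attr(x, "flock_size")))
  wide <- tapply(x$light, list(x$experiment_id, x$compartment),
                 function(l) toupper(substr(l, 1, 1)))
  print(data.frame(experiment = rownames(wide),
                   thermal = x$thermal[match(rownames(wide), x$experiment_id)],
                   A = wide[, "A"], B = wide[, "B"], C = wide[, "C"],
                   row.names = NULL))
  invisible(x)
}

#' Total scheduled experimentation days
#'
#' @param design an \code{\link{epc_design}}.
#' @return experiments x days-per-treatment x replicates (54 for the default
#'   design).
#' @export
schedule_days <- function(design) {
  length(unique(design$experiment_id)) *
    attr(design, "days_per_treatment") * attr(design, "replicates")
}

#' Total monitored video hours
#'
#' Scheduled days times daily windowed hours times number of compartments
#' (one camera each): 54 days x 4 h/day x 3 compartments = 648 h under the
#' default design and windows.
#'
#' @param design an \code{\link{epc_design}}.
#' @param windows observation windows (see \code{\link{observation_windows}}).
#' @return monitored hours across all cameras.
#' @export
schedule_hours <- function(design, windows = observation_windows()) {
  hours_per_day <- sum(windows$end_s - windows$start_s) / 3600
  schedule_days(design) * hours_per_day * length(unique(design$compartment))
}

#' Total analyzed frames
#'
#' @param design an \code{\link{epc_design}}.
#' @param windows observation windows.
#' @param fps effective (post-down-sampling) frame rate; 15 by default.
#' @return number of frames in the analyzed data set (about 35 million under
#'   the default schedule at 15 fps).
#' @export
schedule_frames <- function(design, windows = observation_windows(),
                            fps = 15) {
  schedule_hours(design, windows) * 3600 * fps
}

#' Attach treatment metadata to stream records
#'
#' Joins a detection stream, count series or unrest series against the design
#' to annotate each record with its \code{light} color (from experiment x
#' compartment) and \code{temperature} (thermal condition of the experiment).
#'
#' @param df data frame with \code{experiment_id} and \code{compartment}
#'   columns.
#' @param design an \code{\link{epc_design}}.
#' @return \code{df} with \code{light} and \code{temperature} columns added.
#' @export
annotate_treatments <- function(df, design) {
  key <- paste(df$experiment_id, df$compartment)
  dkey <- paste(design$experiment_id, design$compartment)
  hit <- match(key, dkey)
  if (anyNA(hit[!is.na(df$experiment_id)]))
    stop("records reference experiments/compartments absent from the design")
  df$light <- design$light[hit]
  df$temperature <- design$thermal[hit]
  df
}

#' Read / write a design configuration
#'
#' YAML mirror of the rotation table: per experiment, the thermal condition
#' and the compartment-to-light map.
#'
#' @param design an \code{\link{epc_design}}.
#' @param path file path.
#' @return \code{read_design} returns an \code{epc_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  exps <- lapply(split(design, design$experiment_id), function(d) {
    list(thermal = d$thermal[1], temperature_c = d$temperature_c[1],
         lights = as.list(setNames(d$light, d$compartment)))
  })
  yaml::write_yaml(list(days_per_treatment = attr(design, "days_per_treatment"),
                        replicates = attr(design, "replicates"),
                        flock_size = attr(design, "flock_size"),
                        experiments = exps), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(names(cfg$experiments), function(id) {
    e <- cfg$experiments[[id]]
    data.frame(experiment_id = as.integer(id), thermal = e$thermal,
               temperature_c = e$temperature_c,
               compartment = names(e$lights),
               light = unlist(e$lights, use.names = FALSE))
  }))
  rows <- rows[order(rows$experiment_id, rows$compartment), ]
  rownames(rows) <- NULL
  design <- structure(rows,
                      days_per_treatment = as.integer(cfg$days_per_treatment),
                      replicates = as.integer(cfg$replicates),
                      flock_size = as.integer(cfg$flock_size),
                      class = c("epc_design", "data.frame"))
  validate_design(design)
  design
}
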