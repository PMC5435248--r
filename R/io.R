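#' Read a signaling network from a file
#'
#' Two dialects are supported. SIF: whitespace-delimited lines of
#' `source interaction target`, where multi-word interaction terms are either
#' quoted (`"weakly activates"`) or underscore-joined (`weakly_activates`);
#' a line holding a single name declares an isolated node; `#` starts a
#' comment. CSV: a header row with columns `source,interaction,target`.
#' `dialect = "auto"` picks by file extension, then by sniffing the first
#' data line. Vocabulary substitutions and auto-declared nodes are surfaced
#' as warnings (and available via [validate_network()]).
#'
#' @param path Path to the network file.
#' @param dialect `"auto"` (default), `"sif"` or `"csv"`.
#' @param quiet Passed to [signaling_network()].
#' @return A [signaling_network()].
#' @export
read_network <- function(path, dialect = c("auto", "sif", "csv"),
                         quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_data <- sub("#.*$", "", lines)
  if (all(!nzchar(trimws(lines_data)))) stop("network file is empty: ", path)

  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "sif") "sif"
      else if (ext == "csv") "csv"
      else {
        first <- trimws(lines_data[nzchar(trimws(lines_data))][1])
        if (grepl(",", first, fixed = TRUE)) "csv" else "sif"
      }
  }
  if (dialect == "csv") read_network_csv(path, quiet) else read_network_sif(lines, quiet)
}

read_network_sif <- function(lines, quiet = FALSE) {
  stripped <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(stripped))
  rows <- lapply(which(keep), function(i) {
    fields <- scan(text = stripped[i], what = character(), quiet = TRUE,
                   quote = "\"'", strip.white = TRUE)
    if (!length(fields) %in% c(1L, 3L)) {
      stop("malformed SIF row at line ", i, ": expected 3 fields (or 1 for ",
           "an isolated node), found ", length(fields))
    }
    fields
  })
  nodes_only <- unlist(lapply(rows, function(f) if (length(f) == 1L) f))
  triples <- Filter(function(f) length(f) == 3L, rows)
  edges <- if (length(triples)) {
    data.frame(
      source = vapply(triples, `[`, "", 1L),
      interaction = vapply(triples, `[`, "", 2L),
      target = vapply(triples, `[`, "", 3L),
      stringsAsFactors = FALSE
    )
  } else NULL
  decl <- unique(c(nodes_only,
                   if (!is.null(edges)) c(rbind(edges$source, edges$target))))
  signaling_network(edges, nodes = decl, quiet = quiet)
}

read_network_csv <- function(path, quiet = FALSE) {
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  bad <- which(!is.na(nf) & nf != 3L)
  if (length(bad)) {
    stop("malformed CSV row at line ", bad[1], ": expected 3 fields, found ",
         nf[bad[1]])
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        strip.white = TRUE)
  need <- c("source", "interaction", "target")
  if (!all(need %in% tolower(names(df)))) {
    stop("CSV network file needs header columns source,interaction,target")
  }
  names(df) <- tolower(names(df))
  signaling_network(df[, need], quiet = quiet)
}

#' Write a signaling network to a file
#'
#' Serializes the network using canonical vocabulary terms so that reading
#' the file back yields an identical network (same nodes, same ordered edge
#' list, same weights). In the SIF dialect multi-word terms are
#' underscore-joined and isolated nodes get single-name lines.
#'
#' @param net A [signaling_network()].
#' @param path Output path.
#' @param dialect `"sif"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("sif", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges
  if (dialect == "sif") {
    lines <- character()
    if (nrow(e)) {
      lines <- paste(e$source, gsub(" ", "_", e$term, fixed = TRUE), e$target)
    }
    isolated <- setdiff(net$nodes, unique(c(e$source, e$target)))
    writeLines(c(lines, isolated), path)
  } else {
    utils::write.csv(
      data.frame(source = e$source, interaction = e$term, target = e$target,
                 stringsAsFactors = FALSE),
      path, row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Read a baseline activity profile
#'
#' A two-column CSV (`node,activity`) mapping nodes to initial percentage
#' activities, typically derived from the user's own experimental data.
#' Values must lie in \[0, 100\].
#'
#' @param path Path to the CSV file (header optional).
#' @return A named numeric vector; empty (with a warning) for an empty file.
#' @export
read_baseline_profile <- function(path) {
  if (!file.exists(path)) stop("baseline profile not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(sub("#.*$", "", lines)))]
  if (!length(lines)) {
    warning("baseline profile is empty: ", path, call. = FALSE)
    return(stats::setNames(numeric(), character()))
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        header = grepl("^\\s*node\\s*,", lines[1],
                                       ignore.case = TRUE),
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("baseline profile needs columns node,activity")
  node <- trimws(as.character(df[[1]]))
  value <- suppressWarnings(as.numeric(df[[2]]))
  bad <- is.na(value) | value < 0 | value > 100
  if (any(bad)) {
    stop("baseline activity outside [0, 100] (or non-numeric) for node(s): ",
         paste(node[bad], collapse = ", "))
  }
  stats::setNames(value, node)
}

#' Write trajectory tables
#'
#' Exports a [simulate.signaling_network()] result as CSV. The long format
#' (canonical) has columns `replicate,timepoint,node,activity`; the wide
#' format has one column per node. Replicate indices are 1-based and time
#' points 0-based with 0 = initial state, as noted in the header comment.
#' Activities are printed with fixed decimal precision.
#'
#' @param ts A `trajectory_set`.
#' @param path Output path.
#' @param format `"long"` (default) or `"wide"`.
#' @param digits Decimal places for activities (default 4).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path, format = c("long", "wide"),
                               digits = 4L) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "trajectory_set"))
  df <- as.data.frame(ts)
  df$activity <- formatC(df$activity, format = "f", digits = digits)
  header <- "# replicate indices are 1-based; timepoint 0 is the initial state"
  if (format == "wide") {
    nodes <- dimnames(ts)[[3]]
    wide <- df[df$node == nodes[1], c("replicate", "timepoint")]
    for (n in nodes) wide[[n]] <- df$activity[df$node == n]
    df <- wide
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format trajectory table
#'
#' @param path Path to a CSV written by [write_trajectories()] (long format),
#'   or any CSV with columns `replicate,timepoint,node,activity`.
#' @return A data frame with those four columns.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("replicate", "timepoint", "node", "activity")
  if (!all(need %in% tolower(names(df)))) {
    stop("trajectory file needs columns replicate,timepoint,node,activity")
  }
  names(df) <- tolower(names(df))
  if (any(df$activity < 0 | df$activity > 100)) {
    stop("trajectory activities must lie in [0, 100]")
  }
  df[, need]
}

#' Read a simulation configuration file
#'
#' YAML or JSON (picked by extension) with any of the fields `replicates`,
#' `timepoints`, `noise_pct`, `exponent`, `decay`, `seed`, `perturbations`
#' (a list of `{node, mode, release_step}` entries) and `baseline_profile`
#' (a path to a CSV read with [read_baseline_profile()], resolved relative
#' to the config file). Missing fields take the [sim_config()] defaults.
#'
#' @param path Path to the config file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("config file must be .yaml/.yml or .json")
  }
  perts <- lapply(raw$perturbations, function(p) {
    perturbation(p$node, p$mode, release_step = p$release_step)
  })
  baseline <- NULL
  if (!is.null(raw$baseline_profile)) {
    bp <- raw$baseline_profile
    if (!file.exists(bp)) bp <- file.path(dirname(path), raw$baseline_profile)
    baseline <- read_baseline_profile(bp)
  }
  defaults <- sim_config()
  sim_config(
    n_replicates = raw$replicates %||% defaults$n_replicates,
    n_timepoints = raw$timepoints %||% defaults$n_timepoints,
    noise_pct = raw$noise_pct %||% defaults$noise_pct,
    exponent = raw$exponent %||% defaults$exponent,
    decay = isTRUE(raw$decay),
    perturbations = perts,
    baseline = baseline,
    seed = raw$seed %||% defaults$seed
  )
}
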