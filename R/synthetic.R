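#' Configuration for a synthetic longitudinal connectome cohort
#'
#' Defines the study conditions a generated cohort emulates: a five-group
#' multiple-sclerosis design (healthy controls plus the CIS, RR, SP and PP
#' clinical courses), 84 parcellated regions arranged in six bilateral
#' modules, longitudinal sessions per subject, and group-graded degradation
#' of both edge density and fiber-count strength. Disease severity acts more
#' strongly on within-module (short-range) connections than on between-module
#' ones, so progressive groups lose clustering and local efficiency as well
#' as raw density, which mirrors the nodal alterations reported for
#' progressive MS connectomes.
#'
#' The default design follows a typical longitudinal MS imaging cohort:
#' 24 HC / 12 CIS / 30 RR / 28 SP / 20 PP subjects with 1/5/6/7/6 sessions
#' each (580 scans in total). Severity is 0 for HC and graded over the
#' clinical courses with the secondary-progressive group most affected.
#'
#' @param n_nodes Number of regions (default 84).
#' @param groups Data frame with columns `group`, `n_subjects`, `n_sessions`,
#'   `severity` (severity in `[0, 1]`).
#' @param base_density Expected edge density at severity 0, in `(0, 1]`.
#' @param base_weight_scale Mean fiber count on present edges at severity 0.
#' @param subject_sd Standard deviation of the per-subject random intercept
#'   applied on the log-weight scale.
#' @param session_drift Per-session multiplicative trend on edge weights
#'   (negative values model longitudinal decline).
#' @param c_d Density attenuation constant: expected density is
#'   `base_density * (1 - c_d * severity)`.
#' @param c_w Weight attenuation constant: expected present-edge weight is
#'   `base_weight_scale * exp(intercept) * (1 - c_w * severity) *
#'   (1 + session_drift * session)`.
#' @param nb_size Negative-binomial size (dispersion) of fiber counts.
#' @param module_ratio Within-module vs between-module edge-probability ratio
#'   of the modular template.
#' @param within_exposure How much harder severity hits within-module
#'   connections; between-module exposure is derived so the edge-averaged
#'   exposure is 1 and the aggregate attenuation contracts above hold.
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it deterministically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_nodes = 84,
                          groups = default_groups(),
                          base_density = 0.4,
                          base_weight_scale = 25,
                          subject_sd = 0.2,
                          session_drift = -0.01,
                          c_d = 0.3,
                          c_w = 0.5,
                          nb_size = 5,
                          module_ratio = 3,
                          within_exposure = 1.6,
                          seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_subjects", "n_sessions", "severity") %in% names(groups)))
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  if (any(groups$n_subjects < 1)) stop("subject counts must be >= 1")
  if (any(groups$n_sessions < 1)) stop("session counts must be >= 1")
  if (any(groups$severity < 0 | groups$severity > 1))
    stop("severity values must lie in [0, 1]")
  if (base_density <= 0 || base_density > 1)
    stop("base_density must be in (0, 1]")
  if (base_weight_scale <= 0) stop("base_weight_scale must be positive")
  if (subject_sd < 0) stop("subject_sd must be non-negative")
  structure(list(n_nodes = as.integer(n_nodes), groups = groups,
                 base_density = base_density,
                 base_weight_scale = base_weight_scale,
                 subject_sd = subject_sd, session_drift = session_drift,
                 c_d = c_d, c_w = c_w, nb_size = nb_size,
                 module_ratio = module_ratio,
                 within_exposure = within_exposure,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default five-group MS cohort design
#'
#' @return Data frame with one row per clinical group (HC, CIS, RR, SP, PP).
#' @export
default_groups <- function() {
  data.frame(group = c("HC", "CIS", "RR", "SP", "PP"),
             n_subjects = c(24L, 12L, 30L, 28L, 20L),
             n_sessions = c(1L, 5L, 6L, 7L, 6L),
             severity = c(0, 0.1, 0.45, 1, 0.7),
             stringsAsFactors = FALSE)
}

#' Region labels and module assignment of the modular template
#'
#' For 84 nodes the packaged template (six bilateral lobar modules of 14
#' regions each) is used; other node counts get six contiguous blocks of
#' near-equal size with generic labels.
#'
#' @param n_nodes Number of regions.
#' @return Data frame with columns `node`, `label`, `module`.
#' @export
module_template <- function(n_nodes = 84) {
  if (n_nodes == 84) {
    path <- system.file("extdata", "modular_template_84.csv", package = "msconn")
    tpl <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    module <- sort(rep_len(seq_len(min(6L, n_nodes)), n_nodes))
    tpl <- data.frame(node = seq_len(n_nodes),
                      label = sprintf("node_%02d", seq_len(n_nodes)),
                      module = module)
  }
  tpl
}

# Per-pair structural constants of the generator: edge-probability
# multipliers m (mean 1 over pairs) and severity exposures e (edge-weighted
# mean 1 at severity 0), both block-constant on the module template.
pair_structure <- function(config) {
  tpl <- module_template(config$n_nodes)
  mod <- tpl$module
  within <- outer(mod, mod, "==")
  n_pairs <- config$n_nodes * (config$n_nodes - 1) / 2
  n_within <- sum(within[upper.tri(within)])
  r <- config$module_ratio
  m_between <- n_pairs / (n_within * r + (n_pairs - n_within))
  m_within <- r * m_between
  m <- ifelse(within, m_within, m_between)
  # expected edge shares at severity 0 determine the between exposure
  share_within <- n_within * m_within / n_pairs
  e_w <- config$within_exposure
  e_b <- (1 - share_within * e_w) / (1 - share_within)
  if (e_b < 0) stop("within_exposure too large for this module_ratio")
  e <- ifelse(within, e_w, e_b)
  list(labels = tpl$label, m = m, e = e)
}

#' Generate one synthetic connectome
#'
#' Draws a symmetric integer fiber-count matrix with zero diagonal. Edge
#' presence is Bernoulli per node pair on the modular template with
#' probability `base_density * m_ij * (1 - c_d * severity * e_ij)`; present
#' edges carry `1 + NB(size, mu - 1)` counts with mean
#' `mu = base_weight_scale * exp(subject_intercept) * (1 - c_w * severity *
#' e_ij) * (1 + session_drift * session)`. Averaged over pairs this gives the
#' aggregate contracts documented in [cohort_config()]. Randomness comes from
#' the current R random-number stream; callers control reproducibility with
#' `set.seed()` (as [generate_cohort()] does per subject).
#'
#' @param config A [cohort_config()].
#' @param group Group label present in `config$groups`.
#' @param subject_intercept Subject-level random intercept on log-weights.
#' @param session Zero-based session index.
#' @return A [connectivity_matrix()].
#' @export
generate_connectome <- function(config, group, subject_intercept = 0,
                                session = 0L) {
  stopifnot(inherits(config, "cohort_config"))
  gi <- match(group, config$groups$group)
  if (is.na(gi)) stop(sprintf("unknown group label '%s'", group))
  sev <- config$groups$severity[gi]
  q <- config$n_nodes
  st <- pair_structure(config)
  ut <- upper.tri(matrix(0, q, q))
  m <- st$m[ut]
  e <- st$e[ut]
  p_edge <- pmin(pmax(config$base_density * m * (1 - config$c_d * sev * e), 0), 1)
  mu <- config$base_weight_scale * exp(subject_intercept) *
    pmax(1 - config$c_w * sev * e, 0) *
    max(1 + config$session_drift * session, 0)
  present <- stats::rbinom(length(p_edge), 1L, p_edge)
  w <- numeric(length(p_edge))
  idx <- which(present == 1L)
  if (length(idx)) {
    mu1 <- pmax(mu[idx] - 1, 0)
    w[idx] <- 1 + stats::rnbinom(length(idx), size = config$nb_size, mu = mu1)
  }
  values <- matrix(0, q, q)
  values[ut] <- w
  values <- values + t(values)
  connectivity_matrix(values, node_labels = st$labels)
}

#' Generate a longitudinal synthetic cohort
#'
#' One record per (subject, session). Each subject draws a single random
#' intercept (scale `subject_sd`) reused across all of that subject's
#' sessions; each subject owns a deterministic random-number substream
#' derived from the master seed, so cohorts are reproducible and individual
#' subjects can be regenerated independently.
#'
#' @param config A [cohort_config()].
#' @return List of `subject_record` objects, each with fields `subject_id`,
#'   `group`, `session` (zero-based) and `matrix`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  records <- list()
  subj_counter <- 0L
  for (gi in seq_len(nrow(config$groups))) {
    grp <- config$groups$group[gi]
    for (s in seq_len(config$groups$n_subjects[gi])) {
      subj_counter <- subj_counter + 1L
      subject_id <- sprintf("%s_%03d", grp, s)
      set.seed(subject_substream(config$seed, subj_counter))
      intercept <- stats::rnorm(1L, 0, config$subject_sd)
      for (sess in seq_len(config$groups$n_sessions[gi]) - 1L) {
        mat <- generate_connectome(config, grp, intercept, sess)
        records[[length(records) + 1L]] <-
          structure(list(subject_id = subject_id, group = grp,
                         session = sess, matrix = mat),
                    class = "subject_record")
      }
    }
  }
  records
}

# deterministic per-subject substream seed, kept inside 32-bit range
subject_substream <- function(seed, subject_number) {
  as.integer((as.numeric(seed) * 48271 + subject_number * 7919) %% 2147483647)
}

#' Write a cohort to disk
#'
#' Writes each matrix as a whitespace-delimited square text file and a
#' manifest CSV with header `subject_id,group,session,path`.
#'
#' @param cohort List of subject records from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param graphml Also export each raw graph as GraphML.
#' @param tau Threshold used only for the optional GraphML export.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, graphml = FALSE, tau = 0.35) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort, function(rec) {
    fname <- sprintf("%s_s%02d.txt", rec$subject_id, rec$session)
    write_connectivity(rec$matrix, file.path(dir, fname))
    if (graphml) {
      g <- threshold_graph(rec$matrix, tau)
      write_graphml(g, file.path(dir, sub("\\.txt$", ".graphml", fname)))
    }
    data.frame(subject_id = rec$subject_id, group = rec$group,
               session = rec$session, path = fname,
               stringsAsFactors = FALSE)
  }))
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path Path to a manifest written by [write_cohort()];
#'   matrix paths are resolved relative to the manifest's directory.
#' @return List of subject records.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    structure(list(subject_id = manifest$subject_id[i],
                   group = manifest$group[i],
                   session = manifest$session[i],
                   matrix = load_connectivity(file.path(base, manifest$path[i]))),
              class = "subject_record")
  })
}
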