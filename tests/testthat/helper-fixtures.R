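# fixture builders shared across test files; everything is generated in code

# minimal two-network parcel table (R regions, alternating hemispheres)
toyParcels <- function(R = 4L, networks = c("visual", "control"),
                       overlap = rep("", R)) {
  ParcelTable(data.frame(
    region_id = seq_len(R),
    region_label = sprintf("reg%02d", seq_len(R)),
    hemisphere = rep(c("left", "right"), length.out = R),
    network = rep(networks, length.out = R),
    cluster_overlap = overlap))
}

# FCMatrix straight from a symmetric value matrix
fcFromMatrix <- function(values, subject = "s1", condition = "cond") {
  diag(values) <- 0
  new("FCMatrix", values = values, subjectId = subject, condition = condition,
      nRunsAveraged = 1L, flaggedRegions = integer(0))
}

# adjacency matrix of k disconnected cliques of m nodes, unit weights
cliqueGraph <- function(k = 2L, m = 3L) {
  n <- k * m
  A <- matrix(0, n, n)
  for (b in seq_len(k)) {
    idx <- ((b - 1L) * m + 1L):(b * m)
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  A
}

# a RunTimeSeries with standard-normal confounds and quiet motion
toyRun <- function(data, fd = NULL, events = NULL, seed = 1) {
  Tn <- ncol(data)
  set.seed(seed)
  conf <- data.frame(
    global_signal = rnorm(Tn), csf = rnorm(Tn), white_matter = rnorm(Tn),
    trans_x = rnorm(Tn, 0, 0.05), trans_y = rnorm(Tn, 0, 0.05),
    trans_z = rnorm(Tn, 0, 0.05), rot_x = rnorm(Tn, 0, 0.05),
    rot_y = rnorm(Tn, 0, 0.05), rot_z = rnorm(Tn, 0, 0.05),
    framewise_displacement = if (is.null(fd)) c(0, runif(Tn - 1L, 0.03, 0.08))
                             else fd)
  runTimeSeries(data, conf,
                events = if (is.null(events)) dualconn:::.emptyEvents() else events)
}

# independent trapezoid oracle for the JZS Bayes factor: substitute
# g = u/(1-u) and integrate over u in (0,1) on a fine uniform grid
jzsOracle <- function(t, n, scale = sqrt(2) / 2, grid = 2^15) {
  nu <- n - 1
  r2 <- scale^2
  u <- seq(1e-9, 1 - 1e-9, length.out = grid)
  g <- u / (1 - u)
  logf <- 0.5 * log(r2 / 2) - lgamma(0.5) - 1.5 * log(g) - r2 / (2 * g) -
    0.5 * log(1 + n * g) - ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) -
    2 * log(1 - u)
  f <- exp(logf)
  num <- sum((f[-1] + f[-grid]) / 2) * diff(u)[1]
  num / exp(-((nu + 1) / 2) * log1p(t^2 / nu))
}

# minimal trial-table row builder
trialRows <- function(subject, run, block, task_type, pairing, component,
                      n, correct = TRUE, rt = 500, congruency = NA_character_,
                      difficulty = NA_character_,
                      response = NULL) {
  if (is.null(response))
    response <- if (task_type == "dual") "both"
                else unname(dualconn:::.expectedModality[component])
  data.frame(subject_id = subject, run_id = run, block_id = block,
             task_type = task_type, pairing = pairing,
             component_task = component, congruency = congruency,
             response_modality = response,
             rt = rep_len(rt, n), correct = rep_len(correct, n),
             difficulty = difficulty)
}
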