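# hillgpm

Estimation of Hill-kinetics ODE models of gene regulatory networks (GRNs)
from sparse time-series expression data, for systems biologists who have a
known (or hypothesized) signed network structure and want a quantitative
dynamic model of it.

## The model and the estimator

Gene-product concentrations `x_i` (mM) follow multiplicative Hill
kinetics:

    dx_i/dt = P_i * prod_{j in I_i} h-(x_j; Q_ij, R_ij)
                  * prod_{k in A_i} h+(x_k; Q_ik, R_ik) - S_i x_i

with `h-(x;Q,R) = Q^R / (x^R + Q^R)` (inhibition) and
`h+(x;Q,R) = 1 + x^R / (x^R + Q^R)` (activation).  A network with `N`
genes and `M` edges has `2(M+N)` positive parameters.

Estimation uses the **generalized profiling method**: trajectories are
represented in a B-spline basis; an inner penalized least-squares problem
fits the spline coefficients to the data plus an ODE-fidelity penalty
(weight `lambda`, default 150), and an outer problem fits the parameters
through the profiled coefficients.  Positivity constraints are removed by
estimating logarithms (`P = exp(p)`, ...), so both levels are
unconstrained Levenberg–Marquardt.  Because sparse data leave the problem
underdetermined, the log-parameters are split into `theta_p = (p, q, s)`
and the cooperativity exponents `theta_r = (r)`, estimated alternately
until convergence, with a cheap gradient-matching initialization and a
final joint polish (see `vignette("hillgpm-methods")`).

The nine-gene *E. coli* SOS DNA-damage-response model (43 edges, 104
parameters) ships as an executable fixture with published parameter
estimates and experimental steady-state concentrations.

## Worked example: the SOS steady-state validation

```r
library(hillgpm)
sos <- load_sos()
parameter_count(sos$network)
#>   total theta_p theta_r
#>     104      61      43
tab <- reproduce_table2()
tab
#>     gene experimental     model
#> 1   lexA      11.4710 11.192910
#> 2   recA      11.7950 13.325877
#> 3   recF       8.9750  9.833292
#> 4   rpoS      10.3830  9.642525
#> 5   rpoD       9.4618 11.321422
#> 6  umuDC       7.8192  9.691564
#> 7   dinI       9.9169 11.545071
#> 8    ssB      10.2130 11.334815
#> 9   rpoH       8.5983  9.698781
attr(tab, "sse")
#> [1] 15.79029
```

The `model` column is the steady state of the fitted ODE system solved by
damped fixed-point iteration starting from the experimental column; it
matches the published model values to at most 0.03% relative error, and
the sum of squared errors against experiment (15.79 mM²) matches the
published 15.787.

## Worked example: parameter recovery on synthetic data

```r
bm <- recovery_benchmark(sigma = 0)          # designed 3-gene benchmark
fit <- alternate_estimate(bm$network, bm$data, gpm_config(knots = 60))
fit$loop_iterations                          #> 4  (converged)
max(abs(fit$params_hat$Q - bm$truth$Q) / bm$truth$Q)
#> [1] 0.04032476
```

From 25 noise-free samples the estimator recovers every synthesis rate,
degradation rate and threshold within 4%, reducing the profiled data-fit
objective from ~5.0e2 (heuristic initialization) to 1.0e-5.

## Command line

```sh
exec/hillgpm synth --seed 7 --genes 3 --edges 4 --out demo
exec/hillgpm estimate --network demo/network.tsv --data demo/data.csv --out demo/fit
exec/hillgpm steady-state --fixture sos            # published validation table
exec/hillgpm simulate --network demo/network.tsv --params demo/truth.json \
    --x0 "1,1,1" --tf 20 --out demo/traj.csv
```

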