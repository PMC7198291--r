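# ridkin

Model-based **retinol isotope dilution** (RID): whole-body vitamin A
compartmental kinetics, time-varying RID coefficients, total-body-stores
prediction from a single plasma sample, and validation of the sparse-sampling
"super-person" study design on synthetic populations.

## The problem

Vitamin A status is hard to measure: serum retinol is homeostatically
controlled, and liver biopsy is not an option. RID is the accepted indirect
method — give an oral dose of stable-isotope-labeled vitamin A, wait for it
to mix with body stores, and invert the dilution of the label in plasma
retinol into total body stores (TBS, µmol):

```
TBS = Fa(t) * S(t) / SA_p(t)          (modified isotope-dilution equation)
TLR = F * dose * S * a * (H:D - 1)    (classical Olson equation)
```

where `SA_p` is plasma retinol specific activity (fraction of dose per µmol),
`Fa(t)` is the fraction of the dose absorbed and still present in stores at
sampling time, and `S(t)` is the plasma-to-stores specific-activity ratio.
`Fa` and `S` are time-varying and population-dependent. This package derives
them from a whole-body compartmental model — absorption delay, chylomicron
compartment, plasma retinol, a large and a small storage pool, catabolic
loss — simulated with `deSolve`:

```
Fa(t)  = F(6) + F(7)
S(t)   = [F(5)/M(5)] / {[F(6)+F(7)] / [M(6)+M(7)]}
FaS(t) = Fa(t) * S(t)                  and   TBS = FaS(t) / SA_p(t)
```

with `F(I)` the fraction of dose and `M(I)` the tracee mass in compartment I.
At long times `S(t)` plateaus at `S_eq = R(5,6)/[R(5,4)+R(5,6)]`, the
recycled share of plasma inflow; with zero vitamin A intake the plateau is 1.

For field studies in children the package implements the **super-person**
design: each subject gives just two samples (one at a common time, one at a
randomly assigned schedule time), one model is fitted to the composite
dataset (`minpack.lm` Levenberg–Marquardt on log-parameters), and the fitted
population coefficient `FaS_d` converts every subject's common-time `SA_p`
into an individual TBS estimate. Theoretical subjects with known TBS
(`generate_subjects()`) validate the whole pipeline.

## Worked example

```r
library(ridkin)

p <- example_params()     # illustrative high-intake, high-store child group
steady_state(p)
#> Tracee steady-state masses (umol)
#>   chylomicron m4: 0.0908   plasma m5: 1
#>   large store m6: 2000   small store m7: 2.5
#>   total body stores: 2002

cur <- rid_coefficients(simulate_tracer(p, c(0, 4, 7, 14, 21)), steady_state(p))
cur
#> RID coefficient curves: 5 times over 0-21 d (S_eq = 0.8)
#>  time_d     fa      s    fas
#>       4 0.7085 3.1320 2.2190
#>       7 0.7057 1.6620 1.1730
#>      14 0.7011 0.8845 0.6202
#>      21 0.6972 0.8086 0.5638

predict_tbs(cur, 4, 0.0011)   # a child with SA_p = 0.0011 /umol on day 4
#>   subject_id time   sa_p      tbs coefficient_source
#> 1       <NA>    4 0.0011 2017.449         population
```

Reading the output: by day 4 about 71% of the dose sits in stores
(`fa`), plasma SA is still 3.1-fold higher than store SA (`s`), and dividing
the composite coefficient `fas = 2.22` by the measured specific activity
gives 2017 µmol of total body stores. After the plasma/store crossover
(~day 12 here) `s` falls below 1 toward its equilibrium value 0.8.

An end-to-end synthetic study:

```r
pop <- generate_subjects(example_params(), n = 20, seed = 1)
rep <- run_superstudy(pop, study_design(seed = 1), init = example_params())
rep
#> Super-person RID study: 20 subjects, common sample at 4 d
#>   group true TBS: 2357 umol   predicted: 2059 umol   error: 12.65%
#>   subjects within 25% of true TBS: 65%   Spearman rank r: 0.717
```

A command-line front-end covers the same workflow
(`inst/cli/rid simulate|coefficients|predict|fit|superstudy`); an example
parameter file ships in `inst/extdata/example_params.yaml`.

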