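# arrma

Simultaneous estimation of **A**ssumed **R**eciprocity, **R**eciprocity,
and **M**etaperception **A**ccuracy (ARRMA) from multi-interaction dyadic
designs, built on a full Social Relations Model (SRM) decomposition.

## Who this is for

Researchers analyzing round-robin or block data in which people both
respond to each other *and* predict others' responses to them
(metaperceptions): interpersonal perception, family and small-group
research, intergroup studies.  The package takes raw rating matrices,
partitions them into actor, partner, and relationship effects, and
estimates how strongly people (a) assume their responses are reciprocated,
(b) are actually reciprocated, and (c) know how others respond to them —
at the individual level and within specific dyads.

## The model

A directed measurement decomposes as

    X_ijk = mu_k + alpha_ik + beta_jk + gamma_ijk + eps_ijk

with group mean mu, actor effect alpha, partner effect beta, and
relationship effect gamma.  Round-robin effects use the least-squares
closed forms that accommodate the missing diagonal, e.g.

    alpha_i = (n-1)^2/(n^2-2n) * M_i. + (n-1)/(n^2-2n) * M_.i - (n-1)/(n-2) * M_..

Individual-level ARRMA is the just-identified system

    alpha_mp = B * alpha_r + C * beta_r + e,    A = cov(alpha_r, beta_r)

and dyadic ARRMA is the analogous system on yoked relationship effects,
up to the full two-outcome model with paths B, B', C, C', reciprocity A,
and disturbance covariance D (reciprocity of metaperceptions).  For
indistinguishable dyads the Olsen–Kenny equality constraints and the
I-SAT (indistinguishable-saturated) model calibrate fit: on pairwise
double-entered data the I-SAT chi-square is identically 0 on 6 df, and on
dyad-format data its chi-square and df are subtracted from the constrained
model's.  All constrained and latent-variable fits run through a built-in
maximum-likelihood covariance-and-mean-structure engine with labeled
equality constraints.  See the methods vignette
(`vignettes/arrma-methods.Rmd`) for the full account.

## Worked example

Simulate the reference design (25 round-robin groups of 4, reciprocal
responses and metaperceptions), decompose, and fit:

```r
library(arrma)

cfg <- sim_config(K = 25, n = 4, seed = 2026)
sim <- simulate_srm_arrma(cfg)
ds  <- pipeline_datasets(sim)     # decompose + assemble datasets

fit_individual_arrma(ds$individual)
#> Individual-level ARRMA (full) | N = 100
#>   unstandardized     se standardized      p
#> B         0.7692 0.0536       0.8498 0.0000
#> A         0.3146 0.1336       0.2825 0.0186
#> C         0.0690 0.0537       0.0760 0.2031
#>   R^2 = 0.765

pw <- to_pairwise(ds$dyads)       # double entry for indistinguishable dyads
fit_full_dyadic_indistinguishable(pw)
#> Full dyadic ARRMA | indistinguishable (Olsen-Kenny constraints) | pairwise entry | N = 300
#>    unstandardized standardized
#> B          0.5615       0.5798
#> B'         0.5615       0.5798
#> A          0.3595       0.3434
#> C          0.1499       0.1548
#> C'         0.1499       0.1548
#> D         -0.2641      -0.4653
#>   R^2(MP) = 0.422, R^2(MP') = 0.422 | chi-square(6) = 0.0000
```

Reading the output: family-style data generated with strong assumed
reciprocity (truth 0.8 individual, 0.6 dyadic), moderate reciprocity
(covariance 0.4), weak accuracy (0.1 / 0.15), and negatively related
metaperception disturbances (−0.2) — the fits recover that pattern.  B is
the regression of one's metaperception on one's own response; C is its
regression on the partner's actual response; A is the reciprocity
covariance (correlation when standardized); D is the covariance of the two
members' metaperception disturbances.  The equality of B and B' (and C and
C') reflects the indistinguishability constraints; the chi-square of 0 on
6 df is the expected I-SAT result for double-entered data.

Real data enter through `read_dyadic_data()` (wide matrices with an empty
diagonal, or long CSV), then the same pipeline:
`decompose_round_robin()` / `decompose_block()`, `composite_effects()`
across indicators, `build_individual_dataset()` / `build_dyad_table()`,
and the `fit_*` functions.  A command-line wrapper ships in
`inst/cli/arrma` (subcommands `decompose`, `fit-individual`, `fit-dyadic`,
`fit-isat`, `simulate`, `recover`).

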