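#!/usr/bin/env python
"""Coalescent back-end for driftpainter's synthetic-data generator.

Reads a JSON demography/run specification, simulates independent regions
with msprime (ancestry + binary mutations), and writes one binary blob:

    for each region:
        int32 n_sites, int32 n_hap,
        int32 positions[n_sites]  (bp, 1-based),
        uint8 alleles[n_hap][n_sites]

plus a JSON sidecar with the per-haploid population labels. Monomorphic
sites are dropped here to keep the transfer small.

Usage: simulate_panel.py <spec.json> <out.bin> <out_meta.json>
"""
import json
import sys

import msprime
import numpy as np


def build_demography(spec):
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
    for ch in spec.get("size_changes", []):
        dem.add_population_parameters_change(
            time=ch["time"], population=ch["population"], initial_size=ch["size"])
    for sp in spec.get("splits", []):
        if sp.get("join"):
            # merge into an already-active population (lineage join)
            for d in sp["derived"]:
                dem.add_mass_migration(
                    time=sp["time"], source=d, dest=sp["ancestral"],
                    proportion=1.0)
        else:
            dem.add_population_split(
                time=sp["time"], derived=sp["derived"],
                ancestral=sp["ancestral"])
    # Forward-time pulse source -> dest at per-generation fraction `rate`
    # over [time_start, time_end] generations ago. Backward in time,
    # lineages currently in `dest` move to `source` at that rate.
    for p in spec.get("pulses", []):
        dem.add_migration_rate_change(
            time=p["time_start"], rate=p["rate"], source=p["dest"], dest=p["source"])
        dem.add_migration_rate_change(
            time=p["time_end"], rate=0.0, source=p["dest"], dest=p["source"])
    # Symmetric ramp: migrant fraction grows linearly by `step` per
    # generation from `duration` generations ago to the present.
    # Encoded as piecewise-constant rates on a 25-generation grid.
    for r in spec.get("ramps", []):
        a, b, step, dur = r["pop_a"], r["pop_b"], r["step"], r["duration"]
        grid = 25.0
        t = 0.0
        while t < dur:
            mid = min(t + grid / 2.0, dur)
            rate = max(step * (dur - mid), 0.0)
            for s, d in ((a, b), (b, a)):
                dem.add_migration_rate_change(time=t, rate=rate, source=s, dest=d)
            t += grid
        for s, d in ((a, b), (b, a)):
            dem.add_migration_rate_change(time=dur, rate=0.0, source=s, dest=d)
    dem.sort_events()
    return dem


def main(spec_path, out_bin, out_meta):
    with open(spec_path) as fh:
        spec = json.load(fh)
    dem = build_demography(spec)
    samples = {k: int(v) for k, v in spec["samples"].items()}
    rng = np.random.default_rng(int(spec["seed"]))

    hap_pops = []
    for name, n in samples.items():
        hap_pops.extend([name] * (2 * n))

    meta = {"hap_pop": hap_pops, "regions": []}
    with open(out_bin, "wb") as out:
        for length in spec["region_lengths"]:
            s1 = int(rng.integers(1, 2**31 - 1))
            s2 = int(rng.integers(1, 2**31 - 1))
            ts = msprime.sim_ancestry(
                samples=samples, demography=dem, sequence_length=length,
                recombination_rate=spec["recombination_rate"], random_seed=s1)
            mts = msprime.sim_mutations(
                ts, rate=spec["mutation_rate"], random_seed=s2,
                model=msprime.BinaryMutationModel())
            G = mts.genotype_matrix()          # sites x haps
            pos = np.array([int(s.position) + 1 for s in mts.sites()],
                           dtype=np.int32)
            freq = G.mean(axis=1)
            keep = (freq > 0) & (freq < 1)
            # positions are bp-unique after integer truncation?
            G, pos = G[keep], pos[keep]
            uniq = np.concatenate(([True], np.diff(pos) > 0))
            G, pos = G[uniq], pos[uniq]
            n_sites, n_hap = G.shape
            out.write(np.int32(n_sites).tobytes())
            out.write(np.int32(n_hap).tobytes())
            out.write(pos.astype(np.int32).tobytes())
            out.write(np.ascontiguousarray(G.T, dtype=np.uint8).tobytes())
            meta["regions"].append({"n_sites": int(n_sites), "n_hap": int(n_hap),
                                    "length": float(length)})
    with open(out_meta, "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
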