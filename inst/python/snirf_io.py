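"""Minimal SNIRF (HDF5) bridge.

Called by the R package via system2; exchanges the time series as raw
little-endian float64 (column-major) plus a JSON sidecar.

Usage:
  python snirf_io.py write <meta.json> <data.raw> <out.snirf>
  python snirf_io.py read  <in.snirf> <meta.json> <data.raw>
"""

import json
import sys

import h5py
import numpy as np


def _str(ds):
    v = ds[()]
    if isinstance(v, bytes):
        return v.decode()
    if isinstance(v, np.ndarray):
        v = v.ravel()[0]
        if isinstance(v, bytes):
            return v.decode()
    return str(v)


def write_snirf(meta_path, data_path, out_path):
    with open(meta_path) as fh:
        meta = json.load(fh)
    n = int(meta["n_samples"])
    nch = int(meta["n_channels"])
    planes = int(meta["n_planes"])
    fs = float(meta["sampling_rate_hz"])
    arr = np.fromfile(data_path, dtype="<f8").reshape((n, nch * planes), order="F")
    with h5py.File(out_path, "w") as f:
        f.create_dataset("formatVersion", data=np.bytes_("1.0"))
        nirs = f.create_group("nirs")
        meta_g = nirs.create_group("metaDataTags")
        meta_g.create_dataset("SubjectID", data=np.bytes_(meta["subject_id"]))
        meta_g.create_dataset("MeasurementDate", data=np.bytes_("unknown"))
        meta_g.create_dataset("MeasurementTime", data=np.bytes_("unknown"))
        meta_g.create_dataset("LengthUnit", data=np.bytes_("cm"))
        meta_g.create_dataset("TimeUnit", data=np.bytes_("s"))
        meta_g.create_dataset("FrequencyUnit", data=np.bytes_("Hz"))
        probe = nirs.create_group("probe")
        probe.create_dataset("wavelengths", data=np.asarray(meta["wavelengths_nm"], float))
        pos = np.zeros((nch, 3))
        pos[:, 0] = np.arange(nch)
        probe.create_dataset("sourcePos3D", data=pos)
        probe.create_dataset("detectorPos3D", data=pos)
        data = nirs.create_group("data1")
        data.create_dataset("dataTimeSeries", data=arr)
        data.create_dataset("time", data=np.arange(n) / fs)
        kind = meta["kind"]  # "od" | "hb" | "intensity"
        for m in range(nch * planes):
            plane = m // nch
            ch = m % nch
            ml = data.create_group("measurementList%d" % (m + 1))
            ml.create_dataset("sourceIndex", data=ch + 1)
            ml.create_dataset("detectorIndex", data=ch + 1)
            if kind == "hb":
                ml.create_dataset("dataType", data=99999)
                ml.create_dataset("dataTypeLabel",
                                  data=np.bytes_(["HbO", "HbR"][plane]))
                ml.create_dataset("dataTypeIndex", data=1)
            elif kind == "od":
                ml.create_dataset("dataType", data=99999)
                ml.create_dataset("dataTypeLabel", data=np.bytes_("dOD"))
                ml.create_dataset("dataTypeIndex", data=1)
                ml.create_dataset("wavelengthIndex", data=plane + 1)
            else:  # raw intensity
                ml.create_dataset("dataType", data=1)
                ml.create_dataset("dataTypeIndex", data=1)
                ml.create_dataset("wavelengthIndex", data=plane + 1)
        events = meta.get("events", [])
        labels = sorted({e["label"] for e in events})
        for si, lab in enumerate(labels):
            st = nirs.create_group("stim%d" % (si + 1))
            st.create_dataset("name", data=np.bytes_(lab))
            rows = [[e["onset_s"], e.get("duration_s", 10.0), 1.0]
                    for e in events if e["label"] == lab]
            st.create_dataset("data", data=np.asarray(rows, float))


def read_snirf(in_path, meta_path, data_path):
    with h5py.File(in_path, "r") as f:
        if "nirs" not in f:
            raise SystemExit("format error: missing /nirs group")
        nirs = f["nirs"]
        data_blocks = [k for k in nirs if k.startswith("data")]
        if len(data_blocks) != 1:
            raise SystemExit("unsupported layout: expected exactly one data block")
        data = nirs[data_blocks[0]]
        t = np.asarray(data["time"])
        if t.size > 2:
            dts = np.diff(t)
            if np.max(np.abs(dts - dts[0])) > 1e-6 * dts[0] + 1e-12:
                raise SystemExit("unsupported layout: non-uniform sampling")
        fs = 1.0 / float(np.mean(np.diff(t))) if t.size > 1 else 1.0
        arr = np.asarray(data["dataTimeSeries"], dtype=float)
        mls = sorted([k for k in data if k.startswith("measurementList")],
                     key=lambda s: int(s[len("measurementList"):]))
        kinds, planes, chans = [], [], []
        for k in mls:
            ml = data[k]
            dt = int(np.asarray(ml["dataType"]).ravel()[0])
            if dt == 1:
                kinds.append("intensity")
                planes.append(int(np.asarray(ml["wavelengthIndex"]).ravel()[0]))
            else:
                lab = _str(ml["dataTypeLabel"])
                if lab in ("HbO", "HbR"):
                    kinds.append("hb")
                    planes.append(1 if lab == "HbO" else 2)
                else:
                    kinds.append("od")
                    planes.append(int(np.asarray(ml["wavelengthIndex"]).ravel()[0]))
            chans.append(int(np.asarray(ml["sourceIndex"]).ravel()[0]))
        if len(set(kinds)) != 1:
            raise SystemExit("unsupported layout: mixed measurement kinds")
        kind = kinds[0]
        n_planes = max(planes)
        uch = sorted(set(chans))
        nch = len(uch)
        # reorder columns to (channel-major within plane)
        order = np.zeros(nch * n_planes, dtype=int)
        for m, (pl, ch) in enumerate(zip(planes, chans)):
            order[(pl - 1) * nch + uch.index(ch)] = m
        arr = arr[:, order]
        wl = list(np.asarray(nirs["probe"]["wavelengths"], float)) \
            if "probe" in nirs and "wavelengths" in nirs["probe"] else []
        events = []
        for k in sorted(nirs.keys()):
            if k.startswith("stim"):
                st = nirs[k]
                lab = _str(st["name"])
                rows = np.atleast_2d(np.asarray(st["data"], float))
                if rows.size == 0:
                    continue
                for r in rows:
                    events.append({"onset_s": float(r[0]),
                                   "duration_s": float(r[1]),
                                   "label": lab})
        events.sort(key=lambda e: e["onset_s"])
        sid = "S01"
        if "metaDataTags" in nirs and "SubjectID" in nirs["metaDataTags"]:
            sid = _str(nirs["metaDataTags"]["SubjectID"])
        meta = {
            "kind": kind,
            "n_samples": int(arr.shape[0]),
            "n_channels": nch,
            "n_planes": n_planes,
            "sampling_rate_hz": fs,
            "subject_id": sid,
            "wavelengths_nm": wl,
            "events": events,
        }
        with open(meta_path, "w") as fh:
            json.dump(meta, fh)
        np.ravel(arr, order="F").astype("<f8").tofile(data_path)


def main():
    mode = sys.argv[1]
    if mode == "write":
        write_snirf(sys.argv[2], sys.argv[3], sys.argv[4])
    elif mode == "read":
        read_snirf(sys.argv[2], sys.argv[3], sys.argv[4])
    else:
        raise SystemExit("unknown mode " + mode)


if __name__ == "__main__":
    main()
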