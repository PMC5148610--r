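cone_id,cbc9_id,label,n_points,terminates_at_cone
cone_001,cbc9_1,invaginating,1,TRUE
cone_001,cbc9_2,invaginating,1,FALSE
cone_002,cbc9_2,invaginating,1,TRUE
cone_002,cbc9_3,invaginating,1,TRUE
cone_003,cbc9_4,invaginating,1,TRUE
cone_003,cbc9_5,invaginating,1,FALSE
cone_004,cbc9_1,invaginating,1,TRUE
cone_004,cbc9_6,invaginating,1,TRUE
cone_005,cbc9_3,invaginating,1,TRUE
cone_005,cbc9_4,invaginating,1,FALSE
cone_006,cbc9_5,invaginating,2,TRUE
cone_007,cbc9_1,invaginating,1,FALSE
cone_008,cbc9_2,invaginating,1,FALSE
cone_009,cbc9_3,invaginating,1,FALSE
cone_010,cbc9_4,invaginating,1,FALSE
cone_011,cbc9_5,invaginating,1,FALSE
cone_012,cbc9_6,invaginating,1,FALSE
cone_013,cbc9_1,invaginating,1,FALSE
cone_014,cbc9_2,invaginating,1,FALSE
cone_015,cbc9_1,peripheral,1,FALSE
cone_016,cbc9_2,peripheral,1,FALSE
cone_017,cbc9_3,peripheral,1,FALSE
cone_018,cbc9_4,peripheral,1,FALSE
cone_019,cbc9_5,peripheral,1,FALSE
cone_020,cbc9_6,peripheral,1,FALSE
cone_021,cbc9_1,peripheral,1,FALSE
cone_022,cbc9_2,peripheral,1,FALSE
cone_023,cbc9_3,peripheral,1,FALSE
cone_024,cbc9_4,peripheral,1,FALSE
cone_025,cbc9_5,peripheral,1,FALSE
cone_026,cbc9_6,peripheral,1,FALSE
cone_027,cbc9_1,peripheral,1,FALSE
cone_028,cbc9_2,peripheral,1,FALSE
cone_029,cbc9_3,peripheral,1,FALSE
cone_030,cbc9_4,peripheral,1,FALSE
cone_031,cbc9_5,peripheral,1,FALSE
cone_032,cbc9_6,peripheral,1,FALSE
cone_033,cbc9_1,peripheral,1,FALSE
cone_034,cbc9_2,peripheral,1,FALSE
cone_035,cbc9_3,peripheral,1,FALSE
cone_036,cbc9_4,peripheral,1,FALSE
cone_037,cbc9_5,peripheral,1,FALSE
cone_038,cbc9_6,peripheral,1,FALSE
cone_039,cbc9_1,peripheral,1,FALSE
cone_040,cbc9_2,peripheral,1,FALSE
cone_041,cbc9_3,peripheral,1,FALSE
cone_042,cbc9_4,peripheral,1,FALSE
cone_043,cbc9_5,peripheral,1,FALSE
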