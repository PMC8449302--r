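# App-id -> category map used for daily app-use durations.
# Categories: active (apps requiring active engagement), information
# (passive information/entertainment consumption), social (social media).
# Apps absent from this map fall into "other" and are excluded from the
# three app feature groups. Edit freely for a real deployment.
com.app.messenger: active
com.app.mail: active
com.app.maps: active
com.android.mms: active
com.google.android.gm: active
com.app.video: information
com.app.browser: information
com.google.android.youtube: information
com.android.chrome: information
org.mozilla.firefox: information
com.app.facegram: social
com.app.snapbook: social
com.facebook.katana: social
com.instagram.android: social
com.snapchat.android: social
com.twitter.android: social
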